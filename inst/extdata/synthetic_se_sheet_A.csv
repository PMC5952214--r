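"tank","day","fish_count","clip_type","shannon_entropy"
1,1,1,"basal1","1,380"
1,1,1,"basal2","0,358"
1,1,1,"basal3","1,837"
1,1,1,"event","2,138"
1,2,1,"basal1","1,450"
1,2,1,"basal2","1,774"
1,2,1,"basal3","1,240"
1,2,1,"event","1,842"
1,3,1,"basal1","1,903"
1,3,1,"basal2","1,858"
1,3,1,"basal3","1,475"
1,3,1,"event","1,796"
1,4,1,"basal1","0,431"
1,4,1,"basal2","0,189"
1,4,1,"basal3","1,509"
1,4,1,"event","0,602"
1,5,1,"basal1","1,965"
1,5,1,"basal2","1,264"
1,5,1,"basal3","2,208"
1,5,1,"event","1,611"
2,1,1,"basal1","0,927"
2,1,1,"basal2","1,632"
2,1,1,"basal3","1,633"
2,1,1,"event","1,254"
2,2,1,"basal1","1,459"
2,2,1,"basal2","1,798"
2,2,1,"basal3","0,629"
2,2,1,"event","1,282"
2,3,1,"basal1","0,346"
2,3,1,"basal2","1,246"
2,3,1,"basal3","1,435"
2,3,1,"event","1,603"
2,4,1,"basal1","0,888"
2,4,1,"basal2","1,545"
2,4,1,"basal3","0,610"
2,4,1,"event","1,478"
2,5,1,"basal1","0,704"
2,5,1,"basal2","1,341"
2,5,1,"basal3","1,212"
2,5,1,"event","0,939"
1,1,5,"basal1","3,136"
1,1,5,"basal2","3,402"
1,1,5,"basal3","3,623"
1,1,5,"event","3,706"
1,2,5,"basal1","3,674"
1,2,5,"basal2","3,363"
1,2,5,"basal3","3,462"
1,2,5,"event","3,499"
1,3,5,"basal1","3,491"
1,3,5,"basal2","3,743"
1,3,5,"basal3","3,578"
1,3,5,"event","3,789"
1,4,5,"basal1","3,958"
1,4,5,"basal2","3,658"
1,4,5,"basal3","3,533"
1,4,5,"event","3,403"
1,5,5,"basal1","3,619"
1,5,5,"basal2","3,524"
1,5,5,"basal3","3,752"
1,5,5,"event","3,671"
2,1,5,"basal1","3,634"
2,1,5,"basal2","3,605"
2,1,5,"basal3","3,457"
2,1,5,"event","3,641"
2,2,5,"basal1","3,458"
2,2,5,"basal2","3,527"
2,2,5,"basal3","3,580"
2,2,5,"event","3,608"
2,3,5,"basal1","3,312"
2,3,5,"basal2","3,537"
2,3,5,"basal3","3,431"
2,3,5,"event","3,450"
2,4,5,"basal1","3,526"
2,4,5,"basal2","3,273"
2,4,5,"basal3","3,552"
2,4,5,"event","3,671"
2,5,5,"basal1","3,315"
2,5,5,"basal2","3,511"
2,5,5,"basal3","3,531"
2,5,5,"event","3,714"
1,1,13,"basal1","3,955"
1,1,13,"basal2","3,942"
1,1,13,"basal3","4,056"
1,1,13,"event","4,219"
1,2,13,"basal1","4,231"
1,2,13,"basal2","4,084"
1,2,13,"basal3","4,156"
1,2,13,"event","3,952"
1,3,13,"basal1","4,246"
1,3,13,"basal2","4,168"
1,3,13,"basal3","4,214"
1,3,13,"event","4,375"
1,4,13,"basal1","4,346"
1,4,13,"basal2","4,127"
1,4,13,"basal3","4,067"
1,4,13,"event","4,121"
1,5,13,"basal1","4,239"
1,5,13,"basal2","4,228"
1,5,13,"basal3","4,144"
1,5,13,"event","4,213"
2,1,13,"basal1","4,410"
2,1,13,"basal2","4,177"
2,1,13,"basal3","4,291"
2,1,13,"event","4,408"
2,2,13,"basal1","4,466"
2,2,13,"basal2","4,348"
2,2,13,"basal3","4,323"
2,2,13,"event","4,165"
2,3,13,"basal1","4,236"
2,3,13,"basal2","4,197"
2,3,13,"basal3","4,009"
2,3,13,"event","4,240"
2,4,13,"basal1","4,173"
2,4,13,"basal2","4,195"
2,4,13,"basal3","4,120"
2,4,13,"event","4,266"
2,5,13,"basal1","4,254"
2,5,13,"basal2","4,422"
2,5,13,"basal3","4,326"
2,5,13,"event","4,206"
1,1,50,"basal1","4,747"
1,1,50,"basal2","4,860"
1,1,50,"basal3","4,942"
1,1,50,"event","4,527"
1,2,50,"basal1","4,669"
1,2,50,"basal2","4,991"
1,2,50,"basal3","4,861"
1,2,50,"event","4,512"
1,3,50,"basal1","4,909"
1,3,50,"basal2","4,581"
1,3,50,"basal3","4,624"
1,3,50,"event","4,353"
1,4,50,"basal1","4,861"
1,4,50,"basal2","4,729"
1,4,50,"basal3","4,946"
1,4,50,"event","4,701"
1,5,50,"basal1","4,683"
1,5,50,"basal2","4,679"
1,5,50,"basal3","4,806"
1,5,50,"event","4,964"
2,1,50,"basal1","4,787"
2,1,50,"basal2","4,552"
2,1,50,"basal3","5,018"
2,1,50,"event","4,916"
2,2,50,"basal1","4,894"
2,2,50,"basal2","4,830"
2,2,50,"basal3","5,012"
2,2,50,"event","4,611"
2,3,50,"basal1","4,710"
2,3,50,"basal2","4,690"
2,3,50,"basal3","4,790"
2,3,50,"event","4,898"
2,4,50,"basal1","4,720"
2,4,50,"basal2","4,812"
2,4,50,"basal3","4,849"
2,4,50,"event","4,821"
2,5,50,"basal1","4,924"
2,5,50,"basal2","4,746"
2,5,50,"basal3","4,901"
2,5,50,"event","4,915"
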