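species,genus,locality,infected,screened
Aedeomyia catastica,Aedeomyia,BA,0,1
Aedes aegypti,Aedes,BN,0,1
Aedes aegypti,Aedes,U,0,13
Aedes albolineatus,Aedes,M,0,3
Aedes albopictus,Aedes,DF,6,10
Aedes albopictus,Aedes,KR,6,10
Aedes albopictus,Aedes,KJ,3,6
Aedes albopictus,Aedes,M,6,11
Aedes annandalei,Aedes,KR,3,4
Aedes annandalei,Aedes,M,8,9
Aedes nr. fumidus,Aedes,SBL,6,10
Aedes gardnerii,Aedes,M,1,1
Aedes malayensis,Aedes,DF,1,2
Aedes malayensis,Aedes,KR,13,16
Aedes malayensis,Aedes,KJ,0,2
Anopheles barbirostris complex,Anopheles,DF,0,2
Anopheles barbirostris complex,Anopheles,M,0,2
Anopheles lesteri,Anopheles,KJ,0,2
Anopheles sinensis,Anopheles,BA,0,12
Armigeres kesseli,Armigeres,KR,3,3
Coquillettidia crassipes,Coquillettidia,DF,2,2
Coquillettidia crassipes,Coquillettidia,KR,6,7
Coquillettidia crassipes,Coquillettidia,KJ,4,4
Culex (Lophoceramyia) spp.,Culex,KR,0,1
Culex (Lophoceramyia) spp.,Culex,KJ,0,2
Culex (Lophoceramyia) spp.,Culex,M,1,9
Culex (Lophoceramyia) spp.,Culex,T,0,2
Culex bitaeniorhynchus,Culex,KR,0,1
Culex brevipalpis,Culex,DF,0,1
Culex brevipalpis,Culex,M,0,2
Culex nigropunctatus,Culex,KJ,0,1
Culex nigropunctatus,Culex,M,0,2
Culex pseudovishnui,Culex,KR,11,12
Culex pseudovishnui,Culex,M,4,4
Culex pseudovishnui,Culex,SBG,3,5
Culex pseudovishnui,Culex,SBL,1,1
Culex quinquefasciatus,Culex,BA,5,8
Culex sitiens,Culex,SBL,2,4
Culex sp.,Culex,M,0,2
Culex tritaeniorhynchus,Culex,KJ,2,5
Culex tritaeniorhynchus,Culex,SBL,0,1
Culex tritaeniorhynchus,Culex,T,0,1
Culex vishnui,Culex,M,0,2
Culex vishnui,Culex,T,0,3
Malaya genurostris,Malaya,BB,2,4
Malaya genurostris,Malaya,KR,0,1
Malaya genurostris,Malaya,KJ,4,13
Malaya genurostris,Malaya,SBG,0,1
Mansonia dives,Mansonia,M,0,2
Mansonia indiana,Mansonia,KJ,3,3
Mimomyia luzonensis,Mimomyia,KJ,0,1
Tripteroides sp.,Tripteroides,KR,0,7
Tripteroides sp.,Tripteroides,M,1,2
Uranotaenia obscura,Uranotaenia,DF,2,4
Uranotaenia obscura,Uranotaenia,M,2,2
Uranotaenia obscura,Uranotaenia,RR,1,1
Uranotaenia sp.,Uranotaenia,DF,1,2
Uranotaenia trilineata,Uranotaenia,M,1,1
Verrallina butleri,Verrallina,KJ,1,1
Verrallina sp.,Verrallina,RR,1,5
Zeugnomyia gracilis,Zeugnomyia,DF,1,2
Zeugnomyia gracilis,Zeugnomyia,M,1,13
Zeugnomyia gracilis,Zeugnomyia,RR,1,4
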