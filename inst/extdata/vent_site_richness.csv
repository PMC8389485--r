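system,site,abbr,alpha
backarc,Alice Springs/Illium,AI,29
backarc,Burke,Bk,23
backarc,Hafa Adai,HA,25
backarc,Perseverance,Pv,13
backarc,Forecast,Fc,20
backarc,Snail,Sn,21
backarc,Archaean,Ar,13
backarc,Urashima/Pika,UP,15
arc,Nikko,Nk,12
arc,Kasuga-2,K2,12
arc,NW Eifuku,NWE,21
arc,Daikoku,Dk,14
arc,Chamorro,Ch,5
arc,East Diamante,ED,16
arc,NW Rota,NWR,9
arc,Seamount X,SX,14
jdf,Explorer,Ex,29
jdf,Middle Valley,MV,46
jdf,Endeavour,En,45
jdf,CoAxial,CA,27
jdf,Axial,Ax,40
jdf,North Cleft,NC,28
jdf,South Cleft,SC,16
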