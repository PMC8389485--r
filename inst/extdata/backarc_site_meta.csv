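site,abbr,latitude,longitude,depth_m,arc_distance_km,neighbor_distance_km,max_temperature_c,venting_area_m2
Alice Springs/Illium,AI,18.21183,144.70750,3597,109,3.5,287,2270
Burke,Bk,18.18250,144.71983,3630,108,136.7,50,2625
Hafa Adai,HA,16.96133,144.86917,3279,101,169.2,345,5165
Perseverance,Pv,15.48000,144.50767,3910,97,239.9,264,510
Forecast,Fc,13.40000,143.91667,1470,23,59.1,210,2510
Snail,Sn,12.95333,143.62000,2850,11,2.7,248,1183
Archaean,Ar,12.93333,143.63333,2990,8,2.3,345,1840
Urashima/Pika,UP,12.91833,143.64833,2956,6,NA,330,1995
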