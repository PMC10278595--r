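band,n_band,animal_id,year,winter_ha,summer_ha,overlap_ha,overlap_pct,distance_km,delta_elev_m,strategy_printed,n_returns
1,1,42696,2019,273.4,2887.8,0.0,0,47.4,-44.0,LDM,0
2,1,42703,2019,610.8,1810.2,0.0,0,41.0,-31.6,LDM,0
3,2,42704,2019,650.8,2476.3,0.0,0,31.3,-257.1,LDM,0
3,2,42701,2019,1195.1,2525.4,0.0,0,30.2,-7.7,LDM,0
4,3,42698,2019,2308.0,10196.2,0.0,0,26.5,-110.2,LDM,0
4,3,41320,2019,1750.1,2732.5,516.3,29.5,,-121.7,ABR,0
4,3,42702,2019,392.6,2453.7,181.0,46.1,,-45.1,ABR,0
5,1,41324,2019,277.9,4925.8,0.0,0,17.3,-6.8,LDM,0
6,2,41318,2019,598.5,2459.2,15.0,2.5,15.2,-43.4,LDM,0
6,2,42699,2019,732.5,3598.0,9.5,1.3,14.0,21.4,LDM,0
7,2,41321,2018,1852.9,6324.1,163.1,8.8,11.4,62.9,V-SDM,3
7,2,41323,2018,1738.8,3191.5,0.0,0,10.7,-44.3,V-SDM,3
8,2,42697,2019,234.5,2770.2,19.9,8.5,7.9,4.9,SDM,0
8,2,42695,2019,233.6,2325.6,22.7,9.7,7.6,6.6,SDM,0
9,2,41322,2019,1559.5,3237.7,506.8,32.5,,7.5,ABR,0
9,2,42700,2019,1521.7,1765.5,1113.9,73.2,,-22.3,ABR,0
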