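region_name,average_latitude,incident_count,prevalent_count,total_esrd_count,gn_esrd_count,population_millions
Austria,47.5,39,151,7947,1162,8.4
Belgium,50.6,28,119,10818,1322,10.8
Denmark,56.0,15,66,4400,600,5.5
Finland,64.0,37,143,4206,596,5.3
France,46.6,334,1350,67500,9643,64.3
Greece,39.0,27,113,12556,1614,11.3
Scotland,56.5,24,99,4500,619,5.2
Italy,42.8,312,1320,62857,8800,60.0
Netherlands,52.2,51,214,15286,2140,16.5
Norway,64.5,29,120,3750,522,4.8
Spain,40.0,129,552,50182,6494,46.0
Sweden,62.0,46,186,7154,1033,9.3
England & Wales,52.5,142,548,45667,6089,54.8
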