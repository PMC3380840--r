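region_name,average_latitude,incident_count,prevalent_count,total_esrd_count,gn_esrd_count,population_millions
White,39.8,1500,3400,340000,50000,200
African American,39.8,160,360,180000,24000,39
Asian American,39.8,330,750,25000,5000,14.7
Native American,39.8,50,120,6000,1100,3.1
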