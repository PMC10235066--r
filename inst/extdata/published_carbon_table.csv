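level,name,additional_gt,additional_se_gt,total_agc_gt,total_agc_se_gt,area_mkm2
globe,Globe,9.64,0.9,61.41,0.3,16.15
continent,South America,4.94,0.47,29.12,0.16,4.49
continent,Asia,1.38,0.59,9.08,0.21,2.05
continent,Africa,1.2,0.17,9.58,0.07,4.33
continent,North America,0.86,0.33,5.99,0.1,2.32
continent,Oceania,0.65,0.32,2.26,0.09,1.65
continent,Europe,0.61,0.13,5.37,0.05,1.32
biome,Tropical and subtropical moist broadleaf forests,5.93,1.59,37.53,0.48,4.46
biome,Temperate broadleaf and mixed forests,1.39,0.64,7.8,0.22,1.39
biome,"Tropical and subtropical grasslands, savannas and shrublands",0.81,0.31,5.25,0.11,3.17
biome,Temperate coniferous forests,0.4,0.13,3.13,0.07,0.55
biome,Tropical and subtropical dry broadleaf forests,0.3,0.06,1.13,0.02,0.32
biome,"Mediterranean forests, woodlands and scrubs",0.28,0.09,0.93,0.06,0.55
biome,Deserts and xeric shrublands,0.25,0.22,1.06,0.09,2.88
biome,Boreal forests/taiga,0.16,0.24,1.73,0.03,0.74
biome,"Temperate grasslands, savannas and shrublands",0.05,0.08,0.26,0.02,0.36
biome,Flooded grasslands and savannas,0.04,0.03,0.22,0.02,0.28
biome,Tropical and subtropical coniferous forests,0.03,0.03,0.51,0.01,0.1
biome,Mangroves,0.01,0.08,0.22,0.03,0.09
biome,Tundra,-0.01,0.02,0.09,0.01,0.74
biome,Montane grasslands and shrublands,-0.01,0.15,1.19,0.04,0.55
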