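name	rank	mean_copy_number
Thermobifida_fusca	species	2
Saccharomonospora_viridis	species	1
Bacillus_subtilis	species	10
Bacillus_licheniformis	species	7
Lactobacillus_brevis	species	5
Sphingomonas_paucimobilis	species	2
Idiomarina_andamanensis	species	4
Thermobifida	genus	2.5
Saccharomonospora	genus	1.5
Bacillus	genus	9.1
Lactobacillus	genus	4.9
Geobacillus	genus	8.2
Sphingomonas	genus	2.1
Idiomarina	genus	3.6
Clostridium	genus	7.4
Paenibacillus	genus	6.8
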