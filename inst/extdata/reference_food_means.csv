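item,mean_hl,sd_hl,mean_ll,sd_ll,p_value,direction
chips,158.9,93.50,120.1,88.90,0.03,1.3
pretzels,26.30,47.60,37.70,60.40,0.40,0.7
grapes,38.00,20.50,25.10,18.30,0.03,1.5
orange_juice,97.10,71.50,86.20,84.70,0.73,1.1
nuts,89.20,110.9,77.20,94.50,0.54,1.2
cucumber,6.400,5.300,6.500,4.700,0.88,1.0
carrot,8.900,11.20,9.600,12.30,0.71,0.9
chocolate,121.5,90.30,113.8,88.30,0.68,1.1
sugar_g,48.30,25.29,42.08,22.63,0.39,1.1
total_kcal,546.2,267.5,476.2,229.1,0.17,1.1
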