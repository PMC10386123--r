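item,kcal_per_100,sugar_per_100
chocolate,450,60
chips,530,0.6
pretzels,380,2
nuts,600,4
grapes,70,16
carrot,35,5
cucumber,15,2
orange_juice,45,9
water,0,0
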