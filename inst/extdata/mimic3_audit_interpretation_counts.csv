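electrolyte,scenario_group,label,n
potassium,non_repletion,above,5790
potassium,non_repletion,within,185666
potassium,non_repletion,below,22410
potassium,repletion,above,27
potassium,repletion,within,6400
potassium,repletion,below,739
magnesium,non_repletion,above,812
magnesium,non_repletion,within,26823
magnesium,non_repletion,below,4729
magnesium,repletion,above,55
magnesium,repletion,within,3041
magnesium,repletion,below,647
phosphate,non_repletion,above,22
phosphate,non_repletion,within,696
phosphate,non_repletion,below,762
phosphate,repletion,above,0
phosphate,repletion,within,7
phosphate,repletion,below,288
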