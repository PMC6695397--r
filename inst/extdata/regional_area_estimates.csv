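class_name,total_ha,concession_ha
oil_palm,75160,49276
rubber,111122,7771
other_trees,3056373,195246
shrub,667310,60853
bare,173866,9013
water,46080,2547
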