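# Reference list of CO2-producing enzyme activities (EC numbers) in plant
# central metabolism. One EC per line; lines starting with '#' are comments.
1.4.4.2    # glycine dehydrogenase (decarboxylating), glycine decarboxylase P-protein
1.2.4.1    # pyruvate dehydrogenase (acetyl-transferring), E1 component
1.2.4.2    # 2-oxoglutarate dehydrogenase, E1 component
1.1.1.42   # isocitrate dehydrogenase (NADP+)
1.1.1.41   # isocitrate dehydrogenase (NAD+)
1.1.1.44   # 6-phosphogluconate dehydrogenase (NADP+, decarboxylating)
1.1.1.40   # malic enzyme (NADP+, oxaloacetate-decarboxylating)
1.1.1.38   # malic enzyme (NAD+)
4.1.1.1    # pyruvate decarboxylase
4.1.1.49   # phosphoenolpyruvate carboxykinase (ATP)
4.1.1.15   # glutamate decarboxylase
1.17.1.9   # formate dehydrogenase
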