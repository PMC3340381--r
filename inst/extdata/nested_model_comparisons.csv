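phenotype,model,delta_minus2logl,delta_df,p_printed,aic_printed
pta,AE,0.000,1,1.000,-2.000
pc1,AE,0.069,1,0.792,-1.931
pc2,AE,1.709,1,0.191,-0.291
pc1_minus_pc2,AE,0.000,1,1.000,-2.000
behl,AE,0.000,1,1.000,-2.000
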