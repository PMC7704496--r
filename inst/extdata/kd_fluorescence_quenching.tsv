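# Dissociation constants of TmCsp complexed with nucleotide heptamers,
# determined by quenching of the intrinsic tryptophan fluorescence assuming
# two independent, identical binding sites per heptamer. K_D is per site.
# c_A_M: total protein concentration used in the titration (NA where the
# protein concentration for that temperature is not on record).
oligonucleotide	temperature_K	kd_uM	kd_se_uM	c_A_M
dA7	303	5.0	0.2	1e-06
dA7	323	19.2	0.5	NA
dA7	343	25.2	0.6	5e-06
dC7	303	2.8	0.1	1e-06
dC7	343	11.0	0.1	5e-06
dG7	303	3.4	0.1	1e-06
dG7	343	5.6	0.1	5e-06
dT7	303	0.0040	0.0002	5e-09
dT7	323	0.44	0.02	NA
dT7	343	1.6	0.04	1e-06
rU7	303	0.0108	0.0008	2.5e-08
rU7	323	1.52	0.01	NA
rU7	343	17.4	0.1	1e-06
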