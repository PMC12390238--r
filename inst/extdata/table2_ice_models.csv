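predicted_species,surrogate_species,r_squared,p_value,mse,cross_validation_success,slope,intercept
Pimephales promelas,Oryzias latipes,0.92,<0.001,0.26,78,1.01,-0.21
Ceriodaphnia dubia,Daphnia magna,0.95,<0.001,0.26,81,1,-0.19
Daphnia pulex,Daphnia magna,0.97,<0.001,0.12,90,1.01,-0.14
Simocephalus serrulatus,Daphnia magna,0.88,<0.001,0.21,87,1,-0.03
Pseudosida ramosa,Daphnia magna,0.87,0.006,0.57,67,0.93,-0.24
Desmodesmus subspicatus,Pseudokirchneriella subcapitata,0.96,<0.001,0.31,84,1.1,-0.11
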