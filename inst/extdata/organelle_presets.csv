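organelle,state,n_cells,protein_mean,protein_sd,dna_mean,dna_sd,rna_mean,rna_sd,lipid_mean,lipid_sd,ratio_mean,ratio_sd,glycogen_mean,glycogen_sd,background_scale,noise_sd,supported
nucleus,live,39,104.6,11.23,12.5,4.0,11.6,2.0,4.5,3.5,0.62,0.11,2.0,1.5,120,1,TRUE
nucleus,formaldehyde_fixed,39,63.0,4.9,9.3,3.2,6.0,1.9,2.0,3.5,NA,NA,2.0,1.5,120,1,TRUE
nucleus,ethanol_fixed,39,67.9,5.5,13.9,3.0,5.6,1.2,0.1,0.4,NA,NA,2.0,1.5,120,1,TRUE
nucleolus,live,58,119.1,13.2,1.9,2.5,34.4,6.5,3.1,3.6,0.65,0.10,2.0,1.5,120,1,TRUE
nucleolus,formaldehyde_fixed,58,92.3,8.0,4.1,2.4,23.4,4.4,0.6,2.1,NA,NA,2.0,1.5,120,1,TRUE
nucleolus,ethanol_fixed,58,114.0,26.8,4.8,3.2,37.2,7.3,0.1,0.9,NA,NA,2.0,1.5,120,1,TRUE
mitochondrion,live,38,100.0,15.5,7.4,3.2,8.5,2.4,15.5,12.1,0.57,0.10,2.0,1.5,120,1,TRUE
mitochondrion,formaldehyde_fixed,38,76.3,10.1,6.5,3.2,7.2,2.4,16.7,6.5,0.58,0.10,2.0,1.5,120,1,TRUE
mitochondrion,ethanol_fixed,38,91.9,12.5,10.7,7.6,5.7,1.0,7.0,10.0,0.63,0.10,2.0,1.5,120,1,TRUE
er,live,38,89.1,11.2,0.2,0.1,9.1,3.3,23.1,6.5,0.54,0.06,2.0,1.5,120,1,TRUE
er,formaldehyde_fixed,38,76.5,12.0,0.3,0.1,10.0,3.1,21.2,7.3,0.55,0.07,2.0,1.5,120,1,TRUE
golgi,live,35,111.5,14.0,0.2,0.1,9.3,2.2,35.4,10.2,0.43,0.05,2.0,1.5,120,1,TRUE
golgi,formaldehyde_fixed,35,79.6,13.1,0.3,0.2,7.7,2.5,41.5,18.2,0.49,0.05,2.0,1.5,120,1,TRUE
mitotic_cytoplasm,live,16,92.1,17.5,0.7,0.7,12.2,2.76,13.6,3.5,0.53,0.10,2.0,1.5,120,1,TRUE
mitotic_cytoplasm,formaldehyde_fixed,16,54.3,8.3,1.7,1.6,6.3,1.7,11.1,9.5,0.51,0.10,2.0,1.5,120,1,TRUE
mitotic_cytoplasm,ethanol_fixed,16,83.4,23.1,0.0,0.0,7.9,6.3,0.0,0.0,NA,NA,2.0,1.5,120,1,TRUE
mitotic_chromosome,live,18,98.1,14.4,20.8,8.5,14.6,2.9,6.2,1.4,0.52,0.10,2.0,1.5,120,1,TRUE
mitotic_chromosome,formaldehyde_fixed,18,51.9,9.0,19.7,3.9,5.0,1.9,4.3,2.7,0.46,0.06,2.0,1.5,120,1,TRUE
mitotic_chromosome,ethanol_fixed,18,67.3,22.1,30.5,10.5,8.5,3.9,3.0,3.0,0.74,0.06,2.0,1.5,120,1,TRUE
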