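name,construct,modality
sdevF0.st,prosody,acoustic
iqrF0.st,prosody,acoustic
meanF0.st,prosody,acoustic
MeanDur_intrapause,pause,acoustic
SdevDur_intrapause,pause,acoustic
pct_intrapause,pause,acoustic
IMC_RTEMP_RMAS_theta_alpha,connectivity,sEMG
IMC_RTEMP_RABD_theta_alpha,connectivity,sEMG
IMC_RABD_RMAS_theta_alpha,connectivity,sEMG
IMC_RTEMP_RMAS_beta,connectivity,sEMG
IMC_RTEMP_RABD_beta,connectivity,sEMG
IMC_RABD_RMAS_beta,connectivity,sEMG
IMC_RTEMP_RMAS_gamma,connectivity,sEMG
IMC_RTEMP_RABD_gamma,connectivity,sEMG
IMC_RABD_RMAS_gamma,connectivity,sEMG
density_RTEMP,amplitude,sEMG
density_RMAS,amplitude,sEMG
density_RABD,amplitude,sEMG
density_audio,amplitude,acoustic
mod_depth_theta_RTEMP,rhythm,sEMG
mod_depth_theta_RMAS,rhythm,sEMG
mod_depth_theta_RABD,rhythm,sEMG
PSI_delta_theta_RTEMP,rhythm,sEMG
PSI_delta_theta_RMAS,rhythm,sEMG
PSI_delta_theta_RABD,rhythm,sEMG
PSI_theta_beta.gamma_RTEMP,rhythm,sEMG
PSI_theta_beta.gamma_RMAS,rhythm,sEMG
PSI_theta_beta.gamma_RABD,rhythm,sEMG
hbenvlp_mod_depth_theta_100_300,rhythm,acoustic
hbenvlp_mod_depth_theta_300_800,rhythm,acoustic
hbenvlp_mod_depth_theta_1000_3000,rhythm,acoustic
hbenvlp_mod_depth_theta_3000_8000,rhythm,acoustic
hbenvlp_PSI_delta_theta_100_300,rhythm,acoustic
hbenvlp_PSI_delta_theta_300_800,rhythm,acoustic
hbenvlp_PSI_delta_theta_1000_3000,rhythm,acoustic
hbenvlp_PSI_delta_theta_3000_8000,rhythm,acoustic
hbenvlp_PSI_theta_beta.gamma_100_300,rhythm,acoustic
hbenvlp_PSI_theta_beta.gamma_300_800,rhythm,acoustic
hbenvlp_PSI_theta_beta.gamma_1000_3000,rhythm,acoustic
hbenvlp_PSI_theta_beta.gamma_3000_8000,rhythm,acoustic
DET_RTEMP,complexity,sEMG
DET_RMAS,complexity,sEMG
DET_RABD,complexity,sEMG
DET_mfcc1,complexity,acoustic
DET_mfcc2,complexity,acoustic
DET_mfcc3,complexity,acoustic
DET_mfcc4,complexity,acoustic
DET_mfcc5,complexity,acoustic
DET_mfcc6,complexity,acoustic
DET_mfcc7,complexity,acoustic
DET_mfcc8,complexity,acoustic
DET_mfcc9,complexity,acoustic
DET_mfcc10,complexity,acoustic
DET_mfcc11,complexity,acoustic
DET_mfcc12,complexity,acoustic
DET_mfcc13,complexity,acoustic
ShanEn_RTEMP,regularity,sEMG
ShanEn_RMAS,regularity,sEMG
ShanEn_RABD,regularity,sEMG
ShanEn_audio,regularity,acoustic
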