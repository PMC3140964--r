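metabolite	formation_energy	concentration
glc_c	-426.7	0.005
g6p_c	-1318.0	NA
f6p_c	-1315.7	NA
dhap_c	-1096.1	NA
pep_c	-1185.5	NA
pyr_c	-352.4	NA
pyr_m	-352.4	NA
oaa_m	-713.0	NA
co2	-547.1	0.0012
accoa_m	-310.0	NA
accoa_c	-310.0	NA
aacoa_m	-360.0	NA
hmgcoa_m	-680.0	NA
acac_m	-294.0	NA
acetone_c	-159.8	NA
acetol_c	-304.0	NA
mglx_c	-187.0	NA
dlacald_c	-318.0	NA
dlac_c	-516.7	NA
coa_m	0.0	NA
coa_c	0.0	NA
g3p_c	-1080.0	NA
glyc_c	-177.8	NA
palm_c	979.2	NA
atp	30.5	0.003
gtp	30.5	NA
nadh_c	220.0	NA
nadh_m	220.0	NA
nadph_c	220.0	NA
fadh2_m	200.0	NA
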