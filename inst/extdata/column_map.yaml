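# Dictionary mapping this package's feature-table column names (keys) to the
# column headers of the published supplementary participant table (values).
# Edit the values to match the downloaded file, place that file at
# inst/extdata/supplementary_dataset.csv, and the reproduction test in
# tests/testthat/test-acceptance.R will run against it.
ct: "CT_s"
ht: "Ht_m"
rsi: "RSI_ms"
stiffness: "Stiffness_Nmkg"
rfd: "RFD_Nskg"
synchro: "Synchro_pct"
imp_ratio: "IMP_ECC_CON"
f_zero_vel: "Fzerovel_Nkg"
hip_ef_gc: "Hip_ExtFlex_GC"
hip_rot_gc: "Hip_ExtIntRot_GC"
hip_ab_gc: "Hip_AbdAdd_GC"
knee_ef_gc: "Knee_ExtFlex_GC"
knee_rot_gc: "Knee_ExtIntRot_GC"
knee_vv_gc: "Knee_ValgusVarus_GC"
ankle_pd_gc: "Ankle_PlaDor_GC"
ankle_ab_gc: "Ankle_AbdAdd_GC"
ankle_ei_gc: "Ankle_EveInv_GC"
ct_ecc: "CT_ECC_s"
imp_ecc: "IMP_ECC_Nskg"
grf_mean_ecc: "MeanGRF_ECC_Nkg"
grf_peak_ecc: "PeakGRF_ECC_Nkg"
disp_ecc: "Disp_ECC_m"
work_ecc: "Work_ECC_Jkg"
hip_rom_ef_ecc: "Hip_ExtFlex_ROM_ECC"
hip_rom_ab_ecc: "Hip_AbdAdd_ROM_ECC"
hip_rom_rot_ecc: "Hip_ExtIntRot_ROM_ECC"
knee_rom_ef_ecc: "Knee_ExtFlex_ROM_ECC"
knee_rom_vv_ecc: "Knee_ValgusVarus_ROM_ECC"
knee_rom_rot_ecc: "Knee_ExtIntRot_ROM_ECC"
ankle_rom_pd_ecc: "Ankle_PlaDor_ROM_ECC"
ankle_rom_ei_ecc: "Ankle_EveInv_ROM_ECC"
ankle_rom_ab_ecc: "Ankle_AbdAdd_ROM_ECC"
ct_con: "CT_CON_s"
imp_con: "IMP_CON_Nskg"
grf_mean_con: "MeanGRF_CON_Nkg"
grf_peak_con: "PeakGRF_CON_Nkg"
disp_con: "Disp_CON_m"
work_con: "Work_CON_Jkg"
hip_rom_ef_con: "Hip_ExtFlex_ROM_CON"
hip_rom_ab_con: "Hip_AbdAdd_ROM_CON"
hip_rom_rot_con: "Hip_ExtIntRot_ROM_CON"
knee_rom_ef_con: "Knee_ExtFlex_ROM_CON"
knee_rom_vv_con: "Knee_ValgusVarus_ROM_CON"
knee_rom_rot_con: "Knee_ExtIntRot_ROM_CON"
ankle_rom_pd_con: "Ankle_PlaDor_ROM_CON"
ankle_rom_ei_con: "Ankle_EveInv_ROM_CON"
ankle_rom_ab_con: "Ankle_AbdAdd_ROM_CON"
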