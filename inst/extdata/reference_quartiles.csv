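dataset,class,feature,q1,median,q3
hfdb,total,d_qrs_dur_ms,-4.0,0.0,8.0
hfdb,total,d_qt_ms,-13.3,1.0,20.3
hfdb,total,d_qrs_max_uv,-149.0,-26.0,86.6
hfdb,total,d_t_max_uv,-65.7,-15.5,39.7
hfdb,total,d_qrs_intg_mvms,-3.9,0.4,5.3
hfdb,total,d_t_intg_mvms,-13.3,-2.7,7.1
hfdb,total,d_qrs_cmplx_pct,-1.2,0.3,1.6
hfdb,total,d_t_cmplx_pct,-1.0,0.4,1.5
hfdb,total,mag_d_vg_mvms,16.1,27.5,41.8
hfdb,total,mag_d_sa_deg,5.3,13.3,27.0
hfdb,total,d_hr_bpm,-5.2,0.4,6.1
hfdb,total,mag_d_j_uv,14.9,24.6,40.3
hfdb,total,d_t_sym_pct,-3.1,-0.1,2.5
hfdb,control,d_qrs_dur_ms,-4.0,0.0,4.5
hfdb,control,d_qt_ms,-13.0,-1.0,13.8
hfdb,control,d_qrs_max_uv,-144.9,-34.2,57.3
hfdb,control,d_t_max_uv,-42.0,-4.6,40.0
hfdb,control,d_qrs_intg_mvms,-3.9,-0.76,3.0
hfdb,control,d_t_intg_mvms,-10.6,0.0,7.1
hfdb,control,d_qrs_cmplx_pct,-1.2,0.0,1.0
hfdb,control,d_t_cmplx_pct,-1.2,0.0,1.0
hfdb,control,mag_d_vg_mvms,14.6,25.0,36.2
hfdb,control,mag_d_sa_deg,3.6,9.1,14.8
hfdb,control,d_hr_bpm,-5.3,-0.7,4.6
hfdb,control,mag_d_j_uv,13.1,21.5,35.3
hfdb,control,d_t_sym_pct,-2.8,-0.2,1.5
hfdb,case,d_qrs_dur_ms,-4.0,4.0,17.0
hfdb,case,d_qt_ms,-15.5,7.5,34.0
hfdb,case,d_qrs_max_uv,-196.4,-11.9,175.7
hfdb,case,d_t_max_uv,-133.9,-48.2,33.2
hfdb,case,d_qrs_intg_mvms,-2.7,3.5,10.8
hfdb,case,d_t_intg_mvms,-19.2,-7.4,8.1
hfdb,case,d_qrs_cmplx_pct,-0.7,1.3,3.4
hfdb,case,d_t_cmplx_pct,0.2,1.6,4.1
hfdb,case,mag_d_vg_mvms,18.1,32.7,50.0
hfdb,case,mag_d_sa_deg,14.9,31.7,56.0
hfdb,case,d_hr_bpm,-2.2,2.9,10.0
hfdb,case,mag_d_j_uv,18.8,32.7,47.4
hfdb,case,d_t_sym_pct,-5.1,0.0,4.1
idb,total,d_qrs_dur_ms,-2.0,0.0,16.0
idb,total,d_qt_ms,-14.0,2.0,16.0
idb,total,d_qrs_max_uv,-131.3,-21.1,79.8
idb,total,d_t_max_uv,-68.1,-9.5,53.5
idb,total,d_qrs_intg_mvms,-2.9,0.0,3.4
idb,total,d_t_intg_mvms,-10.6,-0.6,8.9
idb,total,d_qrs_cmplx_pct,-0.8,0.1,1.1
idb,total,d_t_cmplx_pct,-1.2,0.1,1.4
idb,total,mag_d_vg_mvms,37.5,50.0,65.2
idb,total,mag_d_sa_deg,4.0,9.3,17.2
idb,total,d_hr_bpm,-4.3,1.4,6.5
idb,total,mag_d_j_uv,17.1,25.7,43.5
idb,total,d_t_sym_pct,-2.8,0.2,2.5
idb,control,d_qrs_dur_ms,-4.0,0.0,4.0
idb,control,d_qt_ms,-14.0,2.5,15.0
idb,control,d_qrs_max_uv,-127.9,-12.1,96.1
idb,control,d_t_max_uv,-68.0,-11.4,45.4
idb,control,d_qrs_intg_mvms,-3.3,-0.3,2.8
idb,control,d_t_intg_mvms,-10.7,-0.9,7.5
idb,control,d_qrs_cmplx_pct,-1.0,0.0,0.9
idb,control,d_t_cmplx_pct,-1.1,0.0,1.1
idb,control,mag_d_vg_mvms,38.0,49.6,63.0
idb,control,mag_d_sa_deg,3.7,8.3,15.1
idb,control,d_hr_bpm,-4.9,0.5,5.8
idb,control,mag_d_j_uv,15.1,22.8,35.2
idb,control,d_t_sym_pct,-2.4,0.2,2.1
idb,case,d_qrs_dur_ms,0.0,8.0,17.0
idb,case,d_qt_ms,-17.0,0.0,19.0
idb,case,d_qrs_max_uv,-144.0,-38.9,16.0
idb,case,d_t_max_uv,-70.4,3.0,87.8
idb,case,d_qrs_intg_mvms,-1.5,1.7,9.1
idb,case,d_t_intg_mvms,-10.4,6.6,30.1
idb,case,d_qrs_cmplx_pct,-0.3,0.6,2.8
idb,case,d_t_cmplx_pct,-3.6,0.4,4.4
idb,case,mag_d_vg_mvms,33.4,56.0,86.6
idb,case,mag_d_sa_deg,7.1,15.1,45.5
idb,case,d_hr_bpm,-0.2,4.9,10.1
idb,case,mag_d_j_uv,41.5,68.6,122.7
idb,case,d_t_sym_pct,-4.3,0.8,5.4
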