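stratum,granularity,sensitivity_pct,precision_pct,f1_pct,consistent
All,per_tumor_volume,88.9,51.5,65.3,TRUE
All,per_tumor_cut,82.1,67.6,74.2,TRUE
All,per_slice,84.3,75.5,79.6,TRUE
All,per_patient,92.2,93.2,92.7,TRUE
1-2cm,per_tumor_volume,69.4,45.5,54.9,TRUE
1-2cm,per_tumor_cut,52.4,34.1,41.3,TRUE
1-2cm,per_slice,57.0,39.5,46.7,TRUE
1-2cm,per_patient,72.7,77.4,75.0,TRUE
2-3cm,per_tumor_volume,90.3,57.1,70.0,TRUE
2-3cm,per_tumor_cut,75.0,58.7,65.9,TRUE
2-3cm,per_slice,77.8,66.7,71.7,TRUE
2-3cm,per_patient,92.9,92.9,92.9,TRUE
3-5cm,per_tumor_volume,89.1,49.0,63.2,TRUE
3-5cm,per_tumor_cut,75.7,60.8,67.4,TRUE
3-5cm,per_slice,79.8,69.0,74.0,TRUE
3-5cm,per_patient,94.2,94.2,94.2,TRUE
gt5cm,per_tumor_volume,98.5,54.0,65.7,FALSE
gt5cm,per_tumor_cut,88.1,75.6,81.4,TRUE
gt5cm,per_slice,89.5,84.2,86.8,TRUE
gt5cm,per_patient,100.0,100.0,100.0,TRUE
1tumor,per_tumor_volume,89.2,52.0,65.7,TRUE
1tumor,per_tumor_cut,81.7,66.7,73.4,TRUE
1tumor,per_slice,83.7,74.7,78.9,TRUE
1tumor,per_patient,92.7,93.3,93.0,TRUE
gt1tumor,per_tumor_volume,87.5,49.1,62.9,TRUE
gt1tumor,per_tumor_cut,83.3,70.6,76.4,TRUE
gt1tumor,per_slice,86.0,78.2,82.0,TRUE
gt1tumor,per_patient,89.3,92.6,90.9,TRUE
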