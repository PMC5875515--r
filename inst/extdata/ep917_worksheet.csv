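plaque_id,plaque_type,n_seeds,assay_date,assay_strength_u,measurement_date,activity_mci
1,EP917,17,9/16/2011,115.60,10/23/2011,20.30
2,EP917,17,12/2/2011,51.19,12/8/2011,14.05
3,EP917,15,12/2/2011,40.62,12/8/2011,10.58
4,EP917,15,12/2/2011,36.86,12/8/2011,9.24
5,EP917,6,12/2/2011,43.18,12/8/2011,11.19
6,EP917,17,1/6/2012,65.35,1/10/2012,16.90
7,EP917,17,1/20/2012,70.94,1/23/2012,18.21
8,EP917,17,3/9/2012,59.13,3/8/2012,17.23
9,EP917,17,3/23/2012,53.55,3/22/2012,15.57
10,EP917,17,4/2/2012,47.52,3/30/2012,13.10
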