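# Global ocean hypsometry: cumulative seafloor area fraction (shallowest
# first) against water depth. Reconstructed from the classic 1000-m binned
# global ocean depth-zone area fractions (Menard & Smith): depth-zone shares
# of total ocean area 0-0.2 km 7.5%, 0.2-1 km 4.4%, 1-2 km 4.4%, 2-3 km 8.5%,
# 3-4 km 20.9%, 4-5 km 31.7%, 5-6 km 21.2%, 6-7 km 1.2%, >7 km 0.1%,
# accumulated shallowest-first and normalized to 1. Any user-supplied table
# with the same two columns may be used instead.
depth_m,cum_area_fraction
0,0
100,0.0375
200,0.0750
600,0.0971
1000,0.1192
1500,0.1412
2000,0.1632
2500,0.2057
3000,0.2482
3500,0.3527
4000,0.4573
4500,0.6158
5000,0.7743
5500,0.8803
6000,0.9863
6500,0.9923
7000,0.9983
9000,0.9993
11000,1.0
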