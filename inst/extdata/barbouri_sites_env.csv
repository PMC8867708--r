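site,n_final,latitude,longitude,mean_annual_temp_c,temp_seasonality_c,mean_temp_wettest_quarter_c,elevation_m,soil_organic_carbon_pct,annual_precip_mm
C,23,38.3227,-84.8319,12.49,8.89,21.07,192.19,2.79,1129.44
N,20,39.4861,-84.0277,11.1,9.23,20.09,276.93,3.03,1034.52
S,20,37.2468,-85.1561,13.27,8.4,21.4,260.19,3.38,1333.03
W,23,37.7765,-86.6265,13.12,8.89,12.9,167.46,2.60,1213.07
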