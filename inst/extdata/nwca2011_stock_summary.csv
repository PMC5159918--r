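population,grouping,subpopulation,d0_30,d30_60,d60_90,d90_120,total_0_120,area_Mha
inference,national,Conterminous United States,2.63,2.08,1.76,1.08,7.54,25.2
inference,region,Tidal Saline,0.20,0.17,0.18,0.20,0.76,2.2
inference,region,Coastal Plains,0.83,0.56,0.38,0.28,2.05,10.4
inference,region,EMU,1.24,1.09,0.98,0.55,3.86,8.1
inference,region,Interior Plains,0.27,0.17,0.10,0.07,0.60,3.1
inference,region,West,0.08,0.07,0.08,0.07,0.30,1.4
inference,carbon_type,blue,0.20,0.17,0.18,0.20,0.76,2.2
inference,carbon_type,teal,2.42,1.91,1.59,0.93,6.85,23.0
inference,disturbance,least,0.70,0.58,0.49,0.48,2.25,5.5
inference,disturbance,intermediate,1.29,1.04,0.90,0.52,3.75,12.7
inference,disturbance,most,0.64,0.47,0.37,0.15,1.63,7.0
target,national,Conterminous United States,4.02,3.17,2.68,1.64,11.52,38.4
target,region,Tidal Saline,0.20,0.20,0.22,0.25,0.87,2.7
target,region,Coastal Plains,1.37,0.92,0.64,0.47,3.39,17.1
target,region,EMU,1.53,1.35,1.22,0.68,4.78,10.0
target,region,Interior Plains,0.27,0.26,0.16,0.11,0.80,5.0
target,region,West,0.08,0.19,0.19,0.19,0.66,3.6
target,carbon_type,blue,0.20,0.20,0.22,0.25,0.87,2.7
target,carbon_type,teal,3.25,2.72,2.21,1.45,9.63,35.7
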