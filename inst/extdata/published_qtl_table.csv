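trait,linkage_group,position_cm,nearest_marker,interval_lo,interval_hi,additive,dominance_ratio,pve,tier
Average leaf size,B,52.1,B353,32.6,60.1,0.44,-3.69,8.7,0.05
Average leaf size,H,8.6,H113,0.9,12.5,1.26,0.69,9.9,0.05
Average leaf roundness,D,10,D378,4.6,21.3,0.02,-0.05,10.4,0.05
Average leaf roundness,G,56.3,G154,50.3,62.3,-0.02,-0.36,13.1,0.05
Average leaf roundness,H,4.3,H40,0,8.6,-0.02,-0.37,7.7,0.05
Average leaf roundness,L,105.3,L116,99.7,105.3,-0.02,0.82,4.5,0.05
Spininess,E,48.2,E190,40.1,53.9,1.74,0.13,4.5,0.05
Spininess,H,5.75,H327,0.9,16.5,2.93,-0.21,14.4,0.05
Spininess,L,105.3,L116,103.3,105.3,5.92,0.65,32.7,0.05
Days to flower,D,25.3,D271,15.3,35.3,-0.73,0.06,11.9,0.05
Days to flower,H,8.8,H113,6.7,18.5,0.42,1.25,5.6,0.05
Days to flower,I,35.5,I253,17.9,49.5,-0.49,-0.58,6.4,0.05
Primary capitulum height,A,24,A69,16.0,33.0,-0.67,0,8.7,0.05
Primary capitulum height,A,62.2,A117,58.8,75.0,0.39,-0.8,4.5,0.05
Primary capitulum height,D,0.01,D129,0.0,10.0,-0.61,-0.23,8.7,0.05
Primary capitulum height,D,68.3,D275,49.7,81.6,0.43,0.11,4.5,0.05
Primary capitulum height,H,2.1,H312,0.9,3,0.66,0.57,9.5,0.05
Primary capitulum height,I,41.5,I276,29.5,53.5,-0.64,-0.14,9.9,0.05
Primary capitulum height,L,101.7,L333,97.7,105.3,0.66,1.08,6.1,0.05
Primary disc diameter,A,66.8,A199,64.2,73.0,-0.60,-0.46,9.2,0.05
Primary disc diameter,H,12.5,H113,6.7,18.5,0.76,0.25,12.3,0.05
Primary disc diameter,I,35.5,I253,22.5,47.5,-0.60,0.18,9.6,0.05
Primary disc diameter,L,101.7,L333,95.7,105.3,0.72,0.15,8.2,0.05
Number of heads,H,3,H76,0.0,18.5,-0.56,-1.4,4.8,0.10
Flower color,D,1.3,D234,0.0,2.6,3.70,-0.79,63.4,0.05
Stem height,E,37.2,"E201, E359",22.0,44.8,2.18,-0.01,6.9,0.05
Stem height,H,6.7,H130,0.9,10.5,2.31,0.42,7.8,0.05
Stem height,I,53.2,I276,37.5,57.2,-1.88,0.52,6.3,0.05
Number of internodes,C,47.5,C200,43.1,50.3,-0.63,-0.44,4.4,0.10
Number of internodes,L,105.3,L116,101.7,105.3,-1.46,0.07,15.9,0.05
Internode length,A,41.8,A245,26.0,49.2,-0.14,0.43,7.6,0.05
Internode length,E,43.8,E354,40.1,48.2,0.13,0.32,4.6,0.05
Internode length,L,40.5,"L219, L339",22.5,49,0.10,0.86,4.2,0.10
Internode length,L,105.3,L116,99.7,105.3,0.17,0.1,6.7,0.05
Lowest branch height,G,44.9,G100,36.9,60.3,-0.06,-0.22,5.9,0.05
Number of selfed seed,C,42.6,C278,33.0,44.2,-2.17,7.26,4.2,0.10
Number of selfed seed,H,7.3,H255,0.0,18.5,15.89,-0.14,7.6,0.05
Number of selfed seed,I,13.9,I175,5.5,22.5,13.71,0.29,6.9,0.05
Achene weight,C,42.6,C278,39.3,43.5,-0.33,-21.68,11,0.05
Achene weight,H,7.8,H231,2.1,18.5,1.71,2.51,4.4,0.10
Achene weight,I,0.0,I111,0,3.5,-4.96,0.73,13.1,0.05
Achene weight,K,37.6,K35,34.8,47.6,4.67,0.06,8.2,0.05
Achene length,C,41.3,C120,40.9,42.7,0.08,5.004,10.4,0.05
Achene length,D,62.4,D213,60.4,68.3,0.15,0.813,5.2,0.10
Achene length,I,17.9,I223,5.9,21.9,-0.28,0.155,12.0,0.05
Achene length,K,37.6,K35,36.5,45.6,0.29,-0.349,8.2,0.05
Achene width,C,42.6,C278,33.0,43.5,0.09,2.69,8.6,0.05
Achene width,I,0.0,I111,0.0,1.5,-0.21,0.8,15.3,0.05
Achene width,J,11.1,J232,0.0,11.1,0.13,0.37,5.1,0.05
Achene width,K,37.6,K35,36.5,45.6,0.18,-0.11,6.8,0.05
Seed dormancy,E,48.6,E190,43.8,53.9,-0.47,0.4,9.0,0.05
Seed oil,I,3.9,I203,0.0,11.9,1.61,0.81,6.4,0.10
Seed oil,I,65.4,I92,55.2,71.4,1.67,1.04,10.6,0.05
Seed oil,J,12.2,J232,11.1,14.2,-1.73,0.21,7.2,0.05
Seed oil,L,75.6,L221,67.6,83.6,2.65,1.35,23.2,0.05
Palmitic acid,E,46.4,E140,45.8,53.9,0.27,0.6,7.5,0.05
Oleic acid,C,50.3,C98,31.0,58.1,-1.33,-0.34,6.4,0.05
Oleic acid,G,29.8,G26,17.4,37.0,1.28,0.71,6.3,0.10
Oleic acid,H,5.75,H327,2.1,18.5,-1.55,-0.66,11.0,0.05
Linoleic acid,G,31.8,G110,15.4,32.9,-1.69,0.67,8.6,0.05
Linoleic acid,H,5.75,H327,0.9,18.5,1.47,-0.78,8.7,0.05
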