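trait,wild_mean,cultivar_mean,significant
Rooting rate,3.24,2.41,TRUE
Average leaf size,7.352,12.3,TRUE
Average leaf roundness,0.559,0.412,TRUE
Spininess,0,19.031,TRUE
Days to flower,33.29,31,TRUE
Primary capitulum height,18.97,21.13,TRUE
Primary disc diameter,16.94,16.76,FALSE
Number of heads,8.78,8.63,FALSE
Flower color,5.47,16.88,TRUE
Stem height,32.94,31.36,FALSE
Number of internodes,19.11,12.33,TRUE
Internode length,1.74,2.56,TRUE
Lowest branch height,72,47,TRUE
Number of selfed seed,12.44,68.59,TRUE
Achene weight,33.8,31.2,FALSE
Achene length,6.23,6.63,TRUE
Achene width,3.63,3.38,TRUE
Seed viability,75,84.9,FALSE
Seed dormancy,10.95,4.31,TRUE
Seed oil,21.35,26.29,TRUE
Palmitic acid,6.97,6.78,FALSE
Stearic acid,2.79,2.57,FALSE
Oleic acid,26.69,12.72,FALSE
Linoleic acid,63.55,77.93,FALSE
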