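feature,anova_r2,dose_ng_per_ml,mean_value
somaCount,65.9,0,224
somaCount,65.9,10,249
somaCount,65.9,50,255
somaCount,65.9,100,251
somaCount,65.9,200,221
somaCount,65.9,1000,137
somaArea,62.3,0,56800
somaArea,62.3,10,71600
somaArea,62.3,50,86700
somaArea,62.3,100,97000
somaArea,62.3,200,94900
somaArea,62.3,1000,59100
neuriteLength,94.4,0,80800
neuriteLength,94.4,10,59800
neuriteLength,94.4,50,38500
neuriteLength,94.4,100,25100
neuriteLength,94.4,200,15600
neuriteLength,94.4,1000,8900
neuriteArea,95.3,0,203000
neuriteArea,95.3,10,164000
neuriteArea,95.3,50,119000
neuriteArea,95.3,100,80000
neuriteArea,95.3,200,49000
neuriteArea,95.3,1000,27000
attachmentPoint#,69.5,0,1260
attachmentPoint#,69.5,10,1380
attachmentPoint#,69.5,50,1400
attachmentPoint#,69.5,100,1360
attachmentPoint#,69.5,200,1150
attachmentPoint#,69.5,1000,640
endingPoint#,82.5,0,4400
endingPoint#,82.5,10,3450
endingPoint#,82.5,50,2700
endingPoint#,82.5,100,2550
endingPoint#,82.5,200,2160
endingPoint#,82.5,1000,1470
branchPoint#,91.0,0,49300
branchPoint#,91.0,10,33600
branchPoint#,91.0,50,20900
branchPoint#,91.0,100,15200
branchPoint#,91.0,200,10900
branchPoint#,91.0,1000,7500
Avg_somaArea,76.8,0,250
Avg_somaArea,76.8,10,287
Avg_somaArea,76.8,50,340
Avg_somaArea,76.8,100,388
Avg_somaArea,76.8,200,431
Avg_somaArea,76.8,1000,432
Avg_neuriteLength,88.0,0,372
Avg_neuriteLength,88.0,10,244
Avg_neuriteLength,88.0,50,151
Avg_neuriteLength,88.0,100,100
Avg_neuriteLength,88.0,200,71
Avg_neuriteLength,88.0,1000,65
Avg_neuriteArea,91.3,0,924
Avg_neuriteArea,91.3,10,666
Avg_neuriteArea,91.3,50,470
Avg_neuriteArea,91.3,100,317
Avg_neuriteArea,91.3,200,222
Avg_neuriteArea,91.3,1000,198
Avg_attachmentPoint#,58.4,0,5.62
Avg_attachmentPoint#,58.4,10,5.54
Avg_attachmentPoint#,58.4,50,5.46
Avg_attachmentPoint#,58.4,100,5.42
Avg_attachmentPoint#,58.4,200,5.20
Avg_attachmentPoint#,58.4,1000,4.68
Avg_endingPoint#,68.6,0,20.3
Avg_endingPoint#,68.6,10,14.1
Avg_endingPoint#,68.6,50,10.6
Avg_endingPoint#,68.6,100,10.2
Avg_endingPoint#,68.6,200,9.8
Avg_endingPoint#,68.6,1000,10.8
Avg_branchPoint#,85.1,0,22.7
Avg_branchPoint#,85.1,10,13.7
Avg_branchPoint#,85.1,50,8.2
Avg_branchPoint#,85.1,100,6.0
Avg_branchPoint#,85.1,200,5.0
Avg_branchPoint#,85.1,1000,5.5
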