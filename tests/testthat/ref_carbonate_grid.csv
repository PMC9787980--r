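ta,dic,temperature,salinity,pco2_ref
2100.0,1900.0,-1.80,32.0,167.286077
2100.0,1900.0,1.15,32.0,191.749870
2100.0,1900.0,4.10,32.0,219.059944
2100.0,1900.0,7.05,32.0,249.478267
2100.0,1900.0,10.00,32.0,283.288484
2100.0,1975.0,-1.80,32.0,278.624237
2100.0,1975.0,1.15,32.0,318.786837
2100.0,1975.0,4.10,32.0,363.450041
2100.0,1975.0,7.05,32.0,412.988553
2100.0,1975.0,10.00,32.0,467.801088
2100.0,2050.0,-1.80,32.0,519.757189
2100.0,2050.0,1.15,32.0,592.255593
2100.0,2050.0,4.10,32.0,672.198812
2100.0,2050.0,7.05,32.0,760.065364
2100.0,2050.0,10.00,32.0,856.344513
2100.0,2125.0,-1.80,32.0,1034.036131
2100.0,2125.0,1.15,32.0,1170.573179
2100.0,2125.0,4.10,32.0,1319.094494
2100.0,2125.0,7.05,32.0,1479.987657
2100.0,2125.0,10.00,32.0,1653.604215
2100.0,2200.0,-1.80,32.0,1842.666723
2100.0,2200.0,1.15,32.0,2076.624680
2100.0,2200.0,4.10,32.0,2328.576013
2100.0,2200.0,7.05,32.0,2598.575288
2100.0,2200.0,10.00,32.0,2886.560712
2150.0,1900.0,-1.80,32.0,130.541329
2150.0,1900.0,1.15,32.0,149.741972
2150.0,1900.0,4.10,32.0,171.208775
2150.0,1900.0,7.05,32.0,195.157436
2150.0,1900.0,10.00,32.0,221.822808
2150.0,1975.0,-1.80,32.0,204.522274
2150.0,1975.0,1.15,32.0,234.326878
2150.0,1975.0,4.10,32.0,267.566222
2150.0,1975.0,7.05,32.0,304.547728
2150.0,1975.0,10.00,32.0,345.602394
2150.0,2050.0,-1.80,32.0,350.385216
2150.0,2050.0,1.15,32.0,400.481495
2150.0,2050.0,4.10,32.0,456.070269
2150.0,2050.0,7.05,32.0,517.580468
2150.0,2050.0,10.00,32.0,585.463496
2150.0,2125.0,-1.80,32.0,669.998815
2150.0,2125.0,1.15,32.0,761.878363
2150.0,2125.0,4.10,32.0,862.761657
2150.0,2125.0,7.05,32.0,973.139720
2150.0,2125.0,10.00,32.0,1093.502186
2150.0,2200.0,-1.80,32.0,1292.237424
2150.0,2200.0,1.15,32.0,1460.245391
2150.0,2200.0,4.10,32.0,1642.287827
2150.0,2200.0,7.05,32.0,1838.670496
2150.0,2200.0,10.00,32.0,2049.639320
2200.0,1900.0,-1.80,32.0,104.883368
2200.0,1900.0,1.15,32.0,120.378255
2200.0,1900.0,4.10,32.0,137.721670
2200.0,1900.0,7.05,32.0,157.093817
2200.0,1900.0,10.00,32.0,178.691668
2200.0,1975.0,-1.80,32.0,157.204785
2200.0,1975.0,1.15,32.0,180.274614
2200.0,1975.0,4.10,32.0,206.050140
2200.0,1975.0,7.05,32.0,234.784083
2200.0,1975.0,10.00,32.0,266.750479
2200.0,2050.0,-1.80,32.0,251.356038
2200.0,2050.0,1.15,32.0,287.815060
2200.0,2050.0,4.10,32.0,328.423247
2200.0,2050.0,7.05,32.0,373.538723
2200.0,2050.0,10.00,32.0,423.544421
2200.0,2125.0,-1.80,32.0,443.638412
2200.0,2125.0,1.15,32.0,506.378871
2200.0,2125.0,4.10,32.0,575.800200
2200.0,2125.0,7.05,32.0,652.380254
2200.0,2125.0,10.00,32.0,736.614800
2200.0,2200.0,-1.80,32.0,857.469013
2200.0,2200.0,1.15,32.0,972.919984
2200.0,2200.0,4.10,32.0,1099.109384
2200.0,2200.0,7.05,32.0,1236.508796
2200.0,2200.0,10.00,32.0,1385.572114
2250.0,1900.0,-1.80,32.0,86.105394
2250.0,1900.0,1.15,32.0,98.872959
2250.0,1900.0,4.10,32.0,113.177187
2250.0,1900.0,7.05,32.0,129.170738
2250.0,1900.0,10.00,32.0,147.020983
2250.0,1975.0,-1.80,32.0,124.962538
2250.0,1975.0,1.15,32.0,143.393174
2250.0,1975.0,4.10,32.0,164.012280
2250.0,1975.0,7.05,32.0,187.030147
2250.0,1975.0,10.00,32.0,212.675883
2250.0,2050.0,-1.80,32.0,189.863554
2250.0,2050.0,1.15,32.0,217.645754
2250.0,2050.0,4.10,32.0,248.660815
2250.0,2050.0,7.05,32.0,283.203826
2250.0,2050.0,10.00,32.0,321.593252
2250.0,2125.0,-1.80,32.0,310.841347
2250.0,2125.0,1.15,32.0,355.646541
2250.0,2125.0,4.10,32.0,405.466000
2250.0,2125.0,7.05,32.0,460.712093
2250.0,2125.0,10.00,32.0,521.821922
2250.0,2200.0,-1.80,32.0,564.196664
2250.0,2200.0,1.15,32.0,642.882316
2250.0,2200.0,4.10,32.0,729.638187
2250.0,2200.0,7.05,32.0,824.976586
2250.0,2200.0,10.00,32.0,929.419308
2300.0,1900.0,-1.80,32.0,71.850784
2300.0,1900.0,1.15,32.0,82.539490
2300.0,1900.0,4.10,32.0,94.524688
2300.0,1900.0,7.05,32.0,107.937283
2300.0,1900.0,10.00,32.0,122.921168
2300.0,1975.0,-1.80,32.0,101.820130
2300.0,1975.0,1.15,32.0,116.897419
2300.0,1975.0,4.10,32.0,133.782305
2300.0,1975.0,7.05,32.0,152.652183
2300.0,1975.0,10.00,32.0,173.700992
2300.0,2050.0,-1.80,32.0,149.037228
2300.0,2050.0,1.15,32.0,170.975174
2300.0,2050.0,4.10,32.0,195.503818
2300.0,2050.0,7.05,32.0,222.868056
2300.0,2050.0,10.00,32.0,253.333734
2300.0,2125.0,-1.80,32.0,230.239678
2300.0,2125.0,1.15,32.0,263.804017
2300.0,2125.0,4.10,32.0,301.234896
2300.0,2125.0,7.05,32.0,342.875147
2300.0,2125.0,10.00,32.0,389.092648
2300.0,2200.0,-1.80,32.0,386.954513
2300.0,2200.0,1.15,32.0,442.263933
2300.0,2200.0,4.10,32.0,503.626418
2300.0,2200.0,7.05,32.0,571.508349
2300.0,2200.0,10.00,32.0,646.398607
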