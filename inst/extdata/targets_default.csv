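name,expected_mz,is_internal_standard,is_class
PC 28:0,678.50683125568,FALSE,
PC 30:0,706.53813138328,FALSE,
PC 30:1,704.52248131948,FALSE,
PC 32:0,734.56943151088,FALSE,
PC 32:1,732.55378144708,FALSE,
PC 32:2,730.53813138328,FALSE,
PC 34:1,760.58508157468,FALSE,
PC 34:2,758.56943151088,FALSE,
PC 34:3,756.55378144708,FALSE,
PC 34:4,754.53813138328,FALSE,
PC 36:1,788.61638170228,FALSE,
PC 36:2,786.60073163848,FALSE,
PC 36:3,784.58508157468,FALSE,
PC 36:4,782.56943151088,FALSE,
PC 36:5,780.55378144708,FALSE,
PC 38:2,814.63203176608,FALSE,
PC 38:3,812.61638170228,FALSE,
PC 38:4,810.60073163848,FALSE,
PC 38:5,808.58508157468,FALSE,
PC 38:6,806.56943151088,FALSE,
PC 38:7,804.55378144708,FALSE,
PC 40:4,838.63203176608,FALSE,
PC 40:5,836.61638170228,FALSE,
PC 40:6,834.60073163848,FALSE,
PC 40:7,832.58508157468,FALSE,
PC 40:8,830.56943151088,FALSE,
PC 42:10,854.56943151088,FALSE,
PC 44:12,878.56943151088,FALSE,
PC O-30:0,692.55886682498,FALSE,
PC O-32:0,720.59016695258,FALSE,
PC O-32:1,718.57451688878,FALSE,
PC O-34:1,746.60581701638,FALSE,
PC O-34:2,744.59016695258,FALSE,
PC O-34:3,742.57451688878,FALSE,
PC O-36:2,772.62146708018,FALSE,
PC O-36:3,770.60581701638,FALSE,
PC O-36:4,768.59016695258,FALSE,
PC O-36:5,766.57451688878,FALSE,
PC O-38:4,796.62146708018,FALSE,
PC O-38:5,794.60581701638,FALSE,
PC O-38:6,792.59016695258,FALSE,
PC O-38:7,790.57451688878,FALSE,
PC O-40:6,820.62146708018,FALSE,
PC O-40:7,818.60581701638,FALSE,
SM 32:1,675.54355111238,FALSE,
SM 33:1,689.55920117618,FALSE,
SM 34:0,705.59050130378,FALSE,
SM 34:1,703.57485123998,FALSE,
SM 34:2,701.55920117618,FALSE,
SM 35:1,717.59050130378,FALSE,
SM 36:1,731.60615136758,FALSE,
SM 36:2,729.59050130378,FALSE,
SM 38:1,759.63745149518,FALSE,
SM 39:1,773.65310155898,FALSE,
SM 40:1,787.66875162278,FALSE,
SM 40:2,785.65310155898,FALSE,
SM 41:1,801.68440168658,FALSE,
SM 41:2,799.66875162278,FALSE,
SM 42:1,815.70005175038,FALSE,
SM 42:2,813.68440168658,FALSE,
SM 42:3,811.66875162278,FALSE,
PC 17:0/17:0,762.60073163848,TRUE,PC
SM 30:0,649.52790104858,TRUE,SM
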