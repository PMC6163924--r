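trait,method,d1,d2,d3,d4
dw,canopy_cover,0.76,0.65,0.62,0.50
dw,greenseeker,0.45,0.53,0.55,0.45
dw,spectral_unmixing,NA,0.74,0.70,0.46
dw,ATSAVI,0.30,0.71,0.68,0.43
dw,EPVI,0.29,0.68,0.63,NA
dw,MCARI,0.23,0.50,0.27,NA
dw,MTCI,0.23,0.63,0.76,0.62
dw,NDRE,0.31,0.75,0.75,0.61
dw,NDVI,0.30,0.72,0.68,0.43
dw,PRI,NA,NA,0.58,0.38
dw,REIP,0.25,0.46,0.77,0.67
dw,WBI,NA,0.55,0.71,0.61
dw,contour_map,0.42,0.79,0.81,0.74
nc,canopy_cover,NA,NA,NA,0.19
nc,greenseeker,NA,NA,0.17,NA
nc,spectral_unmixing,NA,NA,0.24,0.21
nc,ATSAVI,NA,NA,0.20,0.34
nc,EPVI,NA,NA,0.17,0.20
nc,MCARI,NA,NA,NA,NA
nc,MTCI,NA,NA,0.35,0.31
nc,NDRE,NA,NA,0.28,0.35
nc,NDVI,NA,NA,0.20,0.34
nc,PRI,NA,NA,0.17,0.25
nc,REIP,NA,NA,0.34,0.30
nc,WBI,NA,NA,0.24,0.36
nc,contour_map,0.37,0.30,0.43,0.49
nup,canopy_cover,0.78,0.67,0.69,0.48
nup,greenseeker,0.45,0.54,0.53,0.46
nup,spectral_unmixing,NA,0.75,0.66,0.40
nup,ATSAVI,0.34,0.72,0.66,0.31
nup,EPVI,0.32,0.69,0.62,NA
nup,MCARI,0.27,0.51,0.31,NA
nup,MTCI,0.25,0.64,0.66,0.52
nup,NDRE,0.34,0.76,0.69,0.50
nup,NDVI,0.34,0.73,0.66,0.32
nup,PRI,NA,NA,0.57,0.30
nup,REIP,0.27,0.48,0.68,0.58
nup,WBI,NA,0.56,0.66,0.51
nup,contour_map,0.45,0.81,0.75,0.68
cc,greenseeker,0.49,0.42,0.73,0.70
cc,spectral_unmixing,NA,0.56,0.63,0.70
cc,ATSAVI,0.25,0.52,0.68,0.56
cc,EPVI,0.23,0.48,0.68,0.35
cc,MCARI,0.21,0.36,0.65,0.35
cc,MTCI,0.14,0.45,0.47,0.40
cc,NDRE,0.25,0.53,0.62,0.50
cc,NDVI,0.25,0.53,0.68,0.56
cc,PRI,NA,NA,0.71,0.56
cc,REIP,0.16,0.37,0.48,0.43
cc,WBI,NA,0.45,0.62,0.39
cc,contour_map,0.42,0.66,0.74,0.74
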