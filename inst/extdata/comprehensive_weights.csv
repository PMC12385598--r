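level,dimension,attribute,weight
dimension,appearance,appearance,17.71
dimension,aroma,aroma,24.77
dimension,taste,taste,26.60
dimension,drinking_sensation,drinking_sensation,30.92
subattribute,aroma,malt,25.88
subattribute,aroma,hop,4.83
subattribute,aroma,fruit,10.35
subattribute,aroma,floral,20.02
subattribute,aroma,sweet,18.61
subattribute,aroma,fermentation,20.31
subattribute,taste,sweetness,26.70
subattribute,taste,sourness,10.33
subattribute,taste,bitterness,21.92
subattribute,taste,umami,13.47
subattribute,taste,astringency,27.59
subattribute,drinking_sensation,smoothness,12.83
subattribute,drinking_sensation,fullness,8.59
subattribute,drinking_sensation,refreshment,9.99
subattribute,drinking_sensation,body_coordination,14.36
subattribute,drinking_sensation,alcohol_warmth,15.45
subattribute,drinking_sensation,persistence,15.53
subattribute,drinking_sensation,prickliness,5.51
subattribute,drinking_sensation,aftertaste,11.81
subattribute,drinking_sensation,foam_fineness,5.94
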