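score,sem,half_sd,mpc,anchor,side,n,mean_change,median_change,eligible
FIS,12.6,10.7,12.5,item1,improvement,50,14.8,12.5,TRUE
FIS,12.6,10.7,12.5,item1,worsening,57,-11.4,-12.5,TRUE
FIS,12.6,10.7,12.5,qlq_item29,improvement,29,15.1,12.5,TRUE
FIS,12.6,10.7,12.5,qlq_item29,worsening,28,-18.8,-25.0,TRUE
FUN,21.1,16.2,11.1,item1,improvement,49,16.3,0.0,FALSE
FUN,21.1,16.2,11.1,item1,worsening,56,-21.6,-22.2,TRUE
FUN,21.1,16.2,11.1,qlq_item29,improvement,28,13.1,0.0,FALSE
FUN,21.1,16.2,11.1,qlq_item29,worsening,28,-24.6,-16.7,TRUE
SOC,18.1,18.8,25.0,item1,improvement,39,13.5,0.0,FALSE
SOC,18.1,18.8,25.0,item1,worsening,46,-20.1,-12.5,TRUE
SOC,18.1,18.8,25.0,qlq_item29,improvement,23,8.7,0.0,FALSE
SOC,18.1,18.8,25.0,qlq_item29,worsening,19,-22.4,0.0,TRUE
FAT,7.5,7.0,4.8,item1,improvement,50,9.2,7.1,TRUE
FAT,7.5,7.0,4.8,item1,worsening,57,-8.7,-4.8,TRUE
FAT,7.5,7.0,4.8,qlq_item29,improvement,30,7.6,7.1,TRUE
FAT,7.5,7.0,4.8,qlq_item29,worsening,28,-18.5,-19.1,TRUE
MDSS,12.9,11.9,2.4,item1,improvement,49,15.0,11.9,TRUE
MDSS,12.9,11.9,2.4,item1,worsening,56,-9.7,-7.1,TRUE
MDSS,12.9,11.9,2.4,qlq_item29,improvement,30,11.6,11.9,TRUE
MDSS,12.9,11.9,2.4,qlq_item29,worsening,26,-13.6,-15.5,TRUE
GEN,8.5,10.5,,item1,improvement,37,13.8,8.5,TRUE
GEN,8.5,10.5,,item1,worsening,46,-12.2,-11.3,TRUE
GEN,8.5,10.5,,qlq_item29,improvement,22,11.6,7.1,TRUE
GEN,8.5,10.5,,qlq_item29,worsening,19,-18.5,-15.0,TRUE
ALL,8.9,10.6,,item1,improvement,36,14.8,10.0,TRUE
ALL,8.9,10.6,,item1,worsening,46,-11.3,-8.4,TRUE
ALL,8.9,10.6,,qlq_item29,improvement,22,11.2,8.9,TRUE
ALL,8.9,10.6,,qlq_item29,worsening,19,-15.6,-15.1,TRUE
TOI,10.0,10.3,,item1,improvement,46,15.1,9.5,TRUE
TOI,10.0,10.3,,item1,worsening,55,-14.8,-13.0,TRUE
TOI,10.0,10.3,,qlq_item29,improvement,28,13.2,7.1,TRUE
TOI,10.0,10.3,,qlq_item29,worsening,26,-19.5,-18.7,TRUE
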