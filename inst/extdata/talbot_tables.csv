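id,sex,abscissa,ree_kcal_day,citation
talbot_weight,both,3,150,Talbot FB (1938) Am J Dis Child 55:455-459 (abridged transcription)
talbot_weight,both,4,210,Talbot FB (1938)
talbot_weight,both,5,270,Talbot FB (1938)
talbot_weight,both,6,330,Talbot FB (1938)
talbot_weight,both,7,390,Talbot FB (1938)
talbot_weight,both,8,445,Talbot FB (1938)
talbot_weight,both,9,495,Talbot FB (1938)
talbot_weight,both,10,545,Talbot FB (1938)
talbot_weight,both,12,625,Talbot FB (1938)
talbot_weight,both,14,665,Talbot FB (1938)
talbot_weight,both,16,720,Talbot FB (1938)
talbot_weight,both,18,780,Talbot FB (1938)
talbot_weight,both,20,830,Talbot FB (1938)
talbot_weight,both,25,940,Talbot FB (1938)
talbot_weight,both,30,1040,Talbot FB (1938)
talbot_weight,both,35,1120,Talbot FB (1938)
talbot_weight,both,40,1190,Talbot FB (1938)
talbot_weight,both,45,1260,Talbot FB (1938)
talbot_weight,both,50,1330,Talbot FB (1938)
talbot_weight,both,55,1400,Talbot FB (1938)
talbot_weight,both,60,1460,Talbot FB (1938)
talbot_weight,both,65,1520,Talbot FB (1938)
talbot_weight,both,70,1580,Talbot FB (1938)
talbot_weight,both,75,1640,Talbot FB (1938)
talbot_height,male,52,140,Talbot FB (1938) (abridged transcription)
talbot_height,male,60,270,Talbot FB (1938)
talbot_height,male,70,400,Talbot FB (1938)
talbot_height,male,80,500,Talbot FB (1938)
talbot_height,male,90,600,Talbot FB (1938)
talbot_height,male,100,700,Talbot FB (1938)
talbot_height,male,110,800,Talbot FB (1938)
talbot_height,male,120,920,Talbot FB (1938)
talbot_height,male,130,1070,Talbot FB (1938)
talbot_height,male,140,1240,Talbot FB (1938)
talbot_height,male,150,1440,Talbot FB (1938)
talbot_height,male,160,1640,Talbot FB (1938)
talbot_height,male,170,1810,Talbot FB (1938)
talbot_height,male,180,1920,Talbot FB (1938)
talbot_height,female,52,135,Talbot FB (1938) (abridged transcription)
talbot_height,female,60,260,Talbot FB (1938)
talbot_height,female,70,385,Talbot FB (1938)
talbot_height,female,80,480,Talbot FB (1938)
talbot_height,female,90,575,Talbot FB (1938)
talbot_height,female,100,670,Talbot FB (1938)
talbot_height,female,110,765,Talbot FB (1938)
talbot_height,female,120,875,Talbot FB (1938)
talbot_height,female,130,1010,Talbot FB (1938)
talbot_height,female,140,1190,Talbot FB (1938)
talbot_height,female,150,1360,Talbot FB (1938)
talbot_height,female,160,1480,Talbot FB (1938)
talbot_height,female,170,1555,Talbot FB (1938)
talbot_height,female,180,1600,Talbot FB (1938)
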