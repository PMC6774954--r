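condition,pair_id,role,position,word,english,cds_frequency
context,cookie_belly,referent,first,kjeks,cookie,20
context,cookie_belly,referent,second,mage,belly,6
context,cookie_belly,related,first,skje,spoon,6
context,cookie_belly,related,second,badekar,bathtub,NA
context,banana_hair,referent,first,banan,banana,107
context,banana_hair,referent,second,haar,hair,47
context,banana_hair,related,first,flaske,bottle,6
context,banana_hair,related,second,tannborste,toothbrush,8
context,apple_foot,referent,first,eple,apple,40
context,apple_foot,referent,second,fot,foot,11
context,apple_foot,related,first,kopp,cup,17
context,apple_foot,related,second,bukse,pants,18
context,bread_leg,referent,first,brod,bread,26
context,bread_leg,referent,second,bein,leg,16
context,bread_leg,related,first,bord,table,4
context,bread_leg,related,second,bleie,diaper,34
frequency,dog_glasses,referent,first,hund,dog,52
frequency,dog_glasses,referent,second,briller,glasses,1
frequency,dog_glasses,related,first,smokk,pacifier,14
frequency,dog_glasses,related,second,pute,pillow,2
frequency,cat_keys,referent,first,katt,cat,35
frequency,cat_keys,referent,second,nokler,keys,1
frequency,cat_keys,related,first,ball,ball,96
frequency,cat_keys,related,second,sol,sun,14
frequency,book_jacket,referent,first,bok,book,107
frequency,book_jacket,referent,second,jakke,jacket,15
frequency,book_jacket,related,first,telefon,phone,41
frequency,book_jacket,related,second,maane,moon,2
frequency,car_couch,referent,first,bil,car,137
frequency,car_couch,referent,second,sofa,couch,2
frequency,car_couch,related,first,vann,water,255
frequency,car_couch,related,second,teppe,carpet,14
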