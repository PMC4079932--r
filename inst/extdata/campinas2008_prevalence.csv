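indicator,sex,age_start,n,prev_pct,lo_pct,hi_pct
poor_srh,men,60,218,9.4,5.8,14.8
poor_srh,men,65,132,12.9,7.6,20.8
poor_srh,men,70,117,13.7,8.5,21.4
poor_srh,men,75,82,14.8,7.3,27.6
poor_srh,men,80,66,12.0,5.6,23.6
poor_srh,women,60,256,10.3,7.0,15.0
poor_srh,women,65,214,12.3,7.7,18.9
poor_srh,women,70,164,12.6,8.5,18.3
poor_srh,women,75,136,16.9,10.9,25.2
poor_srh,women,80,134,10.9,6.4,18.1
global,men,60,218,26.3,16.6,39.0
global,men,65,132,28.5,19.6,39.4
global,men,70,117,43.0,32.9,53.6
global,men,75,82,48.5,33.9,63.5
global,men,80,66,55.3,41.0,68.8
global,women,60,256,32.8,24.9,41.9
global,women,65,214,37.4,30.8,44.4
global,women,70,164,54.2,43.7,64.4
global,women,75,136,60.6,52.2,68.4
global,women,80,134,74.1,64.3,82.0
mild_moderate,men,60,218,21.4,12.2,34.6
mild_moderate,men,65,132,23.1,14.9,33.9
mild_moderate,men,70,117,35.3,25.1,47.1
mild_moderate,men,75,82,33.7,22.0,47.9
mild_moderate,men,80,66,40.5,28.0,54.3
mild_moderate,women,60,256,26.4,19.1,35.3
mild_moderate,women,65,214,31.8,25.5,38.8
mild_moderate,women,70,164,37.3,27.5,48.2
mild_moderate,women,75,136,48.9,39.7,58.1
mild_moderate,women,80,134,43.1,34.3,52.4
severe,men,60,218,4.9,2.4,10.0
severe,men,65,132,5.4,2.4,11.5
severe,men,70,117,7.6,4.1,13.6
severe,men,75,82,14.8,7.5,27.0
severe,men,80,66,14.9,8.4,25.0
severe,women,60,256,6.4,3.5,11.5
severe,women,65,214,5.6,3.4,9.0
severe,women,70,164,17.0,10.8,25.7
severe,women,75,136,11.7,7.1,18.8
severe,women,80,134,31.1,23.4,39.9
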