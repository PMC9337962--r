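"subject_id","sex","bmi","vital_capacity","sit_and_reach","long_jump","sprint_50m","endurance_run","strength_count"
"S00001","female",21.5,2862.8,14.7,189.9,9.2,243.4,39
"S00002","female",22.2,,10.5,175.7,8.8,232.8,32
"S00003","female",20.2,3425.3,15.8,212.1,8.8,197.4,47
"S00004","male",19.5,2818.8,9.7,227.2,7.7,,10
"S00005","female",22,3441.5,15.5,192.9,7.8,209.1,58
"S00006","female",19.6,3200.9,23.7,176.1,8.7,167,54
"S00007","female",26.2,2191.1,0.7,146.5,9.5,271.3,28
"S00008","female",22.1,2558.3,17.7,182.2,7.5,204.7,57
"S00009","female",24.2,3485.1,6.5,175.1,9.1,239.4,28
"S00010","female",20.5,2173.7,10.8,153.2,9.8,260.9,32
"S00011","male",22,3513.3,2.3,215.6,8.6,286,5
"S00012","male",22.6,2887.8,3.3,225.4,,266.6,9
"S00013","male",23,3829.3,4.2,225.1,8.3,271.8,12
"S00014","male",26,4270.1,1.5,221.3,7.4,250.2,11
"S00015","female",19.7,2284.5,16,161.1,9.5,245,30
"S00016","female",23.6,2548.3,8.9,161.9,9.3,272.3,30
"S00017","male",20.3,5044.7,15.9,249.5,6.9,220.5,15
"S00018","male",18.7,,11.4,251.9,6.4,167.4,17
"S00019","female",18.3,3130.9,10.8,169,9.3,254.5,26
"S00020","male",21.6,4636.5,5.7,229.8,8.3,277.2,13
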