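season,time_block,condition,count
Summer,Morning,Treatment,959
Summer,Morning,Control,644
Summer,Midday,Treatment,1090
Summer,Midday,Control,1111
Summer,Afternoon,Treatment,447
Summer,Afternoon,Control,219
Autumn,Morning,Treatment,392
Autumn,Morning,Control,433
Autumn,Midday,Treatment,625
Autumn,Midday,Control,417
Autumn,Afternoon,Treatment,241
Autumn,Afternoon,Control,324
Winter,Morning,Treatment,158
Winter,Morning,Control,184
Winter,Midday,Treatment,325
Winter,Midday,Control,368
Winter,Afternoon,Treatment,230
Winter,Afternoon,Control,361
Spring,Morning,Treatment,528
Spring,Morning,Control,677
Spring,Midday,Treatment,777
Spring,Midday,Control,593
Spring,Afternoon,Treatment,102
Spring,Afternoon,Control,168
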