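unit_id,level,parent_id,nfarms_b1,nfarms_b2,nfarms_b3,nfarms_b4,nfarms_b5,nfarms_b6,nfarms_b7,pop_b1,pop_b2,pop_b3,pop_b4,pop_b5,pop_b6,pop_b7,pop_total
00,national,,41688,3435,2161,1469,2115,1977,10401,244250,116808,146967,201460,683977,1384921,63248402,66026785
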