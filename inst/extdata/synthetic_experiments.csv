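study_id,experiment_id,species,group_label,scoring,count,path_index,is_shortcut,is_adjacent,is_outer,is_cued,is_training,is_excluded,intersects_training,matches_first_turn,reward_side
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,0,1,0,0,1,0,0,0,0,0,1
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,5,2,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,2,3,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,1,4,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,1,5,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,25,6,1,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,4,7,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,1,8,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,0,9,0,1,0,0,0,0,0,1,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,1,10,0,1,0,0,0,0,1,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,0,11,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,0,12,0,0,1,0,0,0,0,1,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,0,13,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,0,14,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,0,15,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,0,16,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,0,17,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_shortcut,rat,simulated,first_choice,0,18,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,1,1,0,0,1,0,0,0,0,0,1
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,0,2,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,1,3,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,1,4,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,1,5,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,0,6,1,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,1,7,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,1,8,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,14,9,0,1,0,0,0,0,0,1,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,15,10,0,1,0,0,0,0,1,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,2,11,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,3,12,0,0,1,0,0,0,0,1,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,0,13,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,0,14,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,0,15,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,0,16,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,0,17,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent,rat,simulated,first_choice,0,18,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,3,1,0,0,1,0,0,0,0,0,1
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,2,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,2,3,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,2,4,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,5,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,6,1,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,1,7,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,3,8,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,14,9,0,1,0,0,0,0,0,1,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,14,10,0,1,0,0,0,0,1,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,11,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,12,0,0,1,0,0,0,0,1,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,13,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,14,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,15,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,16,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,17,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_adjacent2,rat,simulated,first_choice,0,18,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,0,1,0,0,1,0,0,0,0,0,1
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,2,2,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,4,3,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,2,4,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,5,5,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,1,6,1,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,5,7,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,5,8,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,6,9,0,1,0,0,0,0,0,1,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,4,10,0,1,0,0,0,0,1,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,6,11,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,0,12,0,0,1,0,0,0,0,1,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,0,13,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,0,14,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,0,15,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,0,16,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,0,17,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_uniform,rat,simulated,first_choice,0,18,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,17,1,0,0,1,0,0,0,0,0,1
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,2,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,3,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,4,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,2,5,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,6,1,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,7,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,2,8,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,9,0,1,0,0,0,0,0,1,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,10,0,1,0,0,0,0,1,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,2,11,0,0,0,0,0,0,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,16,12,0,0,1,0,0,0,0,1,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,13,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,14,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,15,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,16,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,17,0,0,0,0,0,1,0,0,0
synthetic_demo,synthetic_outer,rat,simulated,first_choice,0,18,0,0,0,0,0,1,0,0,0
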