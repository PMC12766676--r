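study_id,experiment_id,n_no_choice,provenance
synthetic_demo,synthetic_shortcut,0,simulated
synthetic_demo,synthetic_adjacent,0,simulated
synthetic_demo,synthetic_adjacent2,1,simulated
synthetic_demo,synthetic_uniform,0,simulated
synthetic_demo,synthetic_outer,1,simulated
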