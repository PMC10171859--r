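group,n_lesions,n_remyelinated_mri
treated,21,10
untreated,19,8
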