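source	target	evidence	dataset_id
gp53	gp2	proximity_labeling	chma_miniturboid
gp53	gp61	proximity_labeling	chma_miniturboid
gp53	gp63	proximity_labeling	chma_miniturboid
gp53	gp62	proximity_labeling	chma_miniturboid
gp53	gp148	proximity_labeling	chma_miniturboid
gp53	gp138	proximity_labeling	chma_miniturboid
gp53	gp358	proximity_labeling	chma_miniturboid
gp2	gp53	gfp_pulldown	gp2_gfp
gp2	gp136	gfp_pulldown	gp2_gfp
gp2	gp148	gfp_pulldown	gp2_gfp
gp2	gp63	gfp_pulldown	gp2_gfp
gp2	gp64	gfp_pulldown	gp2_gfp
gp2	gp138	gfp_pulldown	gp2_gfp
gp2	gp358	gfp_pulldown	gp2_gfp
gp53	gp138	gfp_pulldown	chma_gfp
gp53	gp358	gfp_pulldown	chma_gfp
gp62	gp63	gfp_pulldown	gp62_gfp
gp2	gp148	coexpression_pulldown	his6_coexpression
gp2	gp53	coexpression_pulldown	his6_coexpression
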