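module	group
auditory	sensory-motor
somatomotor-hand	sensory-motor
somatomotor-mouth	sensory-motor
visual	sensory-motor
cingulo-opercular	association
default-mode	association
dorsal-attention	association
fronto-parietal	association
salience	association
ventral-attention	association
memory-retrieval	other
subcortical	other
cerebellar	other
uncertain	other
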