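# CNS areas reported abnormal at neuroimaging in Hashimoto's
# encephalopathy / SREAT; used by the expression cross-reference.
frontal lobe
cerebral cortex
frontal cortex
temporal lobe
brain
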