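entity	disease
IL-6	diabetes/insulin resistance
IL-6	obesity
IL-6	metabolic syndrome X
IL-8	diabetes/insulin resistance
IL-8	obesity
IL-8	metabolic syndrome X
TNFa	diabetes/insulin resistance
TNFa	obesity
TNFa	metabolic syndrome X
fetuinA	diabetes/insulin resistance
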