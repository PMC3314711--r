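# Level-0 decision counts on the 1,388-document independent benchmark
predicted_curatable: 642
confirmed_curatable: 287
predicted_uncuratable: 746
curatable_missed: 14
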