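"sex","age","weight"
"female",40,1
"female",41,1
"female",42,1
"female",43,1
"female",44,1
"female",45,1
"female",46,1
"female",47,1
"female",48,1
"female",49,1
"female",50,1
"female",51,1
"female",52,1
"female",53,1
"female",54,1
"female",55,1
"female",56,1
"female",57,1
"female",58,1
"female",59,1
"female",60,1
"female",61,1
"female",62,1
"female",63,1
"female",64,1
"female",65,1
"female",66,1
"female",67,1
"female",68,1
"female",69,1
"female",70,1
"female",71,1
"female",72,1
"female",73,1
"female",74,1
"female",75,1
"female",76,1
"female",77,1
"female",78,1
"female",79,1
"female",80,1
"female",81,1
"female",82,1
"female",83,1
"female",84,1
"female",85,1
"male",40,1
"male",41,1
"male",42,1
"male",43,1
"male",44,1
"male",45,1
"male",46,1
"male",47,1
"male",48,1
"male",49,1
"male",50,1
"male",51,1
"male",52,1
"male",53,1
"male",54,1
"male",55,1
"male",56,1
"male",57,1
"male",58,1
"male",59,1
"male",60,1
"male",61,1
"male",62,1
"male",63,1
"male",64,1
"male",65,1
"male",66,1
"male",67,1
"male",68,1
"male",69,1
"male",70,1
"male",71,1
"male",72,1
"male",73,1
"male",74,1
"male",75,1
"male",76,1
"male",77,1
"male",78,1
"male",79,1
"male",80,1
"male",81,1
"male",82,1
"male",83,1
"male",84,1
"male",85,1
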