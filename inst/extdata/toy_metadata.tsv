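specimen_id	species	genus	family	latitude	longitude	locality
AL01-1	Alpha una	Alpha	Alphidae	-26.1	-54.1	MS
AL01-2	Alpha una	Alpha	Alphidae	-26.2	-54.2	MS
AL01-3	Alpha una	Alpha	Alphidae	-26.3	-54.3	MS
AL01-4	Alpha una	Alpha	Alphidae	-26.4	-54.4	MS
AL02-1	Alpha dua	Alpha	Alphidae	-26.5	-54.5	MS
AL02-2	Alpha dua	Alpha	Alphidae	-27.5	-55.5	FM
AL02-3	Alpha dua	Alpha	Alphidae	-26.6	-54.6	MS
BE01-1	Beta sola	Beta	Betidae	-27	-55	FM
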