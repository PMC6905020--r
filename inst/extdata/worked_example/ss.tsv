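synth001	HEHCHHHHCHCCEEHHHHCHEHHHCHCCHECCHHHECCEECHEHHEEHCECHHCCH
synth002	HCEHCECHHCCCHHCHCEHCCCCHHHCCCECHCHCCECEHHC
synth003	CECCCECHCHECHEHHHCECCCEECCHCCECCHHCCCCHEC
synth004	CHHCCECHECEHHCHHCHCCHCHCCEHHHCCHEHCECCHCCHHHCHCHCHCCCCCHHHC
synth005	HHCCCCECEECHCCCHHCCHHCCHHCHEECCECCECHHHC
synth006	CHHHEHCCECHEHHHCECHCCCHCHCCCHCHHECECCHCCHHHHCCHCEHHCHEHHHE
synth007	CHCECHEHCHHCEHHHHHHCCCHHHHCCCHCEECHECCCEECHHHEHEHCE
synth008	HEEHEECEEEHCHCHHECHCHCECHCHHHCCCHHEECCECCCHHECCHCEHCCCHHHEHC
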