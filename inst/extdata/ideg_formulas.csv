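formula,set
C13H18O7N0S0P0,neg
C14H20O7N0S0P0,neg
C14H20O8N0S0P0,neg
C15H22O8N0S0P0,neg
C15H22O9N0S0P0,neg
C16H24O8N0S0P0,pos
C17H26O8N0S0P0,pos
C17H26O9N0S0P0,pos
C18H28O9N0S0P0,pos
C19H30O10N0S0P0,pos
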