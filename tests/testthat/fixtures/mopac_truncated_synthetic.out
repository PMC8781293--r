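 *******************************************************************************
 ** Synthetic truncated output fixture (hand-written for parser tests)      **
 *******************************************************************************

 PM7 1SCF MOZYME CHARGE=0 EPS=78.4
 protein-ligand complex single point

          SCF CYCLE 14   ENERGY SO FAR -10442.1
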