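 *******************************************************************************
 ** Synthetic single-point output fixture (hand-written for parser tests;   **
 ** mimics the layout of a semiempirical program's result file)             **
 *******************************************************************************

 PM7 1SCF MOZYME CHARGE=0 EPS=78.4
 protein-ligand complex single point

          GEOMETRY OPTIMISATION DISABLED (1SCF)

          FINAL HEAT OF FORMATION =      -4523.91854 KCAL/MOL

          TOTAL ENERGY            =      -104392.11221 EV
          ELECTRONIC ENERGY       =      -893311.00712 EV
          DIPOLE                  =          4.10221 DEBYE

 == MOPAC DONE ==
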