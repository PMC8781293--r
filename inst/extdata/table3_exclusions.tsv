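pdb_id	reason
2Z8D	paradigm_failed_pm7
2ZFS	paradigm_failed_pm7
4LL3	paradigm_failed_pm7
4MR5	paradigm_failed_pm7
5CSD	paradigm_failed_pm7
4CRC	no_experimental_enthalpy
3KIV	no_experimental_enthalpy
4CRD	no_experimental_enthalpy
2PYM	positive_experimental_enthalpy
2PYN	positive_experimental_enthalpy
1J84	distorted_pyranose_ring
2Z8E	distorted_pyranose_ring
4P8V	distorted_pyranose_ring
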