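Query         COQ2_HUMAN Q96H96 4-hydroxybenzoate polyprenyltransferase, mitochondrial
Match_columns 371
No_of_seqs    1234 out of 5678
Neff          9.1
Searched_HMMs 85718
Date          (synthetic reconstruction: hit ids and which entries clear the
Command       50% probability bar follow the published search summary; the
              probability, score and range values themselves are invented)

 No Hit                             Prob E-value P-value  Score    SS Cols Query HMM  Template HMM
  1 4OD4_A UbiA homolog (apo)      99.1 1.2E-22 3.1E-27  185.3   0.0  251   22-280    15-272 (289)
  2 4TQ3_B UbiA homolog            98.7 4.5E-21 1.2E-25  176.8   0.0  248   24-278    11-263 (281)
  3 6M31_B DGGGP synthase          97.2 2.1E-18 5.5E-23  158.4   0.0  239   30-276    18-259 (278)
  4 8DJM_B UbiA domain protein 1   95.4 8.8E-16 2.3E-20  141.2   0.0  230   33-270    41-277 (338)
  5 7E1V_H supercomplex subunit    64.9 1.1E-02 2.9E-07   48.7   0.0  102   60-165    12-115 (146)
  6 7Q21_f cyt c oxidase subunit   61.3 2.3E-02 6.0E-07   45.1   0.0   98   62-162     9-108 (135)
  7 4TQ3_B UbiA homolog region 2   55.2 6.7E-02 1.7E-06   41.3   0.0   64  290-355   201-266 (281)
  8 1FAK_A tissue factor           43.0 2.2E-01 5.7E-06   33.9   0.0   58   91-150    30-89  (211)
  9 2BBB_B decoy hit               12.0 8.5E+00 2.2E-04   19.8   0.0   41  100-142    55-97  (160)
 10 3CCC_C noise-level hit          8.8 1.6E+01 4.1E-04   16.2   0.0   33  110-144    21-55  (90)

No 1
>4OD4_A UbiA homolog (apo)
(alignment blocks omitted; this reconstruction carries the summary table only)
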