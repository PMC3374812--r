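# Relative recurrence-score weight table.
# Group weights are the published values of Paik et al. (2004),
# N Engl J Med 351:2817-26 (reference-derived, not fitted here).
# Edit freely: groups combine member genes by their mean z-score;
# `genes` lists individually weighted genes.
groups:
  her2:
    genes: [HER2, GRB7]
    weight: 0.47
  er:
    genes: [ER, PGR, BCL2, SCUBE2]
    weight: -0.34
  proliferation:
    genes: [Ki67, STK15, Survivin, CCNB1, MYBL2]
    weight: 1.04
  invasion:
    genes: [MMP11, CTSL2]
    weight: 0.10
genes:
  CD68: 0.05
  GSTM1: -0.08
  BAG1: -0.07
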