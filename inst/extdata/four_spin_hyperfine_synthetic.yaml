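# SYNTHETIC placeholder hyperfine tensors for the four-spin flavin-tryptophan
# radical pair (MHz, 3x3 row-major). These are axial stand-ins representative
# of the magnitude and sign of literature couplings for the flavin N5/N10 and
# tryptophan N1/H1 positions (N5 matches the one-nitrogen model); they are
# NOT refined tensors and are expected to be overridden with
# spectroscopically or DFT-derived values via four_spin_model(tensors = ...).
tensors:
  N5:
    - [-2.6, 0.0, 0.0]
    - [0.0, -2.6, 0.0]
    - [0.0, 0.0, 49.2]
  N10:
    - [-0.5, 0.0, 0.0]
    - [0.0, -0.5, 0.0]
    - [0.0, 0.0, 18.0]
  N1:
    - [-1.2, 0.0, 0.0]
    - [0.0, -1.2, 0.0]
    - [0.0, 0.0, 9.0]
  H1:
    - [-10.0, 0.0, 0.0]
    - [0.0, -10.0, 0.0]
    - [0.0, 0.0, -20.0]
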