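# ELA amplicon panel: one entry per primer pair.
# insert_length is the amplicon size after primer removal (bp); pool_ratio is
# the fraction of the sequencing library allocated to the amplicon
# (30:30:10:10:10:10 across the panel); frame_offset is the registered
# translation frame of the insert.
amplicons:
  - name: MHCI_For1Rev2.2
    gene: MHCI
    fwd_primer: GTYGGCTAYGTGGACGAC
    rev_primer: SCCMTCYAGGTAGKYCCT
    insert_length: 378
    pool_ratio: 0.30
    frame_offset: 0
  - name: MHCI_For3.2Rev1
    gene: MHCI
    fwd_primer: GGGCCGSARTATTGGGA
    rev_primer: CTCCAGGTRTCTGMGGAGC
    insert_length: 318
    pool_ratio: 0.30
    frame_offset: 0
  - name: DRA
    gene: DRA
    fwd_primer: CAGCTGTCCTGATGAGCTTT
    rev_primer: AGCCACGTGACATCGATCAC
    insert_length: 360
    pool_ratio: 0.10
    frame_offset: 0
  - name: DRB
    gene: DRB
    fwd_primer: GAGGCTCCTGGATGGCAGCT
    rev_primer: GTCTTTGCAGGATACACAGT
    insert_length: 341
    pool_ratio: 0.10
    frame_offset: 0
  - name: DQA
    gene: DQA
    fwd_primer: GATCCTAAACAGAGCTCTGA
    rev_primer: AAGACAGATGAGGGTGTTGG
    insert_length: 370
    pool_ratio: 0.10
    frame_offset: 0
  - name: DQB
    gene: DQB
    fwd_primer: GGCCTTTGGACAKYAGCT
    rev_primer: RGATGGGGAGAYGGTCAC
    insert_length: 351
    pool_ratio: 0.10
    frame_offset: 0
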