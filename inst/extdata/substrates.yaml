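# Fork substrate geometry presets: 20-bp duplex throughout.
# fork_equal    equal 30/30 nt arms, encircled strand Cy3-labelled at the
#               5' duplex end.
# fork_3long    30-nt 3'-arm, 8-nt 5'-arm (loading restricted to the
#               translocating strand).
# fork_5long    8-nt 3'-arm, 30-nt 5'-arm, excluded strand Cy5-labelled at
#               the 3' duplex end.
# fork_sf       stopped-flow fork: 30-nt 3'-arm with a biotin/streptavidin
#               block 15 nt from the junction, 7-nt 5'-arm carrying the FAM
#               reporter at its end.
fork_equal:
  duplex_len: 20
  arm3_len: 30
  arm5_len: 30
  labelled_strand: encircled_3arm
fork_3long:
  duplex_len: 20
  arm3_len: 30
  arm5_len: 8
  labelled_strand: encircled_3arm
fork_5long:
  duplex_len: 20
  arm3_len: 8
  arm5_len: 30
  labelled_strand: excluded_5arm
fork_sf:
  duplex_len: 20
  arm3_len: 30
  arm5_len: 7
  labelled_strand: encircled_3arm
  block_pos: 15
  reporter_pos: 7
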