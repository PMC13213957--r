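# Carbohydrate HET-code vocabulary.
# Seeded with the monosaccharides dominant in the structural databases
# (pyranoses: glucose, galactose, mannose, xylose, fucose, sialic acid,
# GlcNAc, GalNAc, KDO). Extend freely; matching is case-insensitive.
sugar_codes:
  - GLC   # alpha-D-glucose
  - BGC   # beta-D-glucose
  - GAL   # beta-D-galactose
  - GLA   # alpha-D-galactose
  - MAN   # alpha-D-mannose
  - BMA   # beta-D-mannose
  - XYS   # alpha-D-xylose
  - XYP   # beta-D-xylose
  - FUC   # alpha-L-fucose
  - FUL   # beta-L-fucose
  - SIA   # N-acetylneuraminic (sialic) acid
  - NAG   # N-acetyl-D-glucosamine
  - NGA   # N-acetyl-D-galactosamine
  - KDO   # 3-deoxy-D-manno-oct-2-ulosonic acid
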