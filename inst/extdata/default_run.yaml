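# Reference operating point of the perforated-membrane biosensor model.
# Exactly one of `dimensionless` or `dimensional` may be given.
version: 1
geometry:
  shape: concave_paraboloid_up
  alpha: 0.95        # perforation level, throat radius a2 = 1 - alpha
  gamma: 0.5         # enzyme filling level of the holes
  a3: 0.1            # hole mouth radius (fixed across sweeps)
  b1: 2.0            # selective-membrane top
  b2: 4.0            # perforated-membrane bottom / enzyme-slab top
  b4: 14.0           # perforated-membrane top
  b5: 16.0           # external diffusion-layer top
dimensionless:
  sigma2: 33300.0    # diffusion modulus (Damkohler number), 3.33e4
  S0: 1.0            # bulk substrate concentration / Km
  D2: 3.0            # enzyme-layer diffusivity ratio
  D3: 6.0            # diffusion-layer diffusivity ratio
solver:
  profile: fast
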