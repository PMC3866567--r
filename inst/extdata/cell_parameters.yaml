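# Versioned parameter file for cdgamma cell models.
#
# Units: lengths um, diameters um, axial resistivity ohm*cm, capacitance uF/cm^2,
# channel densities mS/cm^2, reversal potentials mV, time constants ms.
# z_factor is the cosine of the angle between a compartment and the apical
# (pia-directed) axis: +1 apical/soma, 0 oblique, negative for basilar dendrites.
# Channel kinetics are Traub-Miles / Bush-Sejnowski-lineage forms; the rate
# equations are fixed in the integrator and their constants are listed under
# `kinetics` for reference.
version: 1

axial_resistivity: 200.0

capacitance:
  l23_pyramidal: 0.85
  l5_pyramidal: 0.85
  basket: 1.0

reversal:
  na: 50.0
  k: -90.0
  ca: 120.0
  h: -45.0
  gabaa: -80.0
  ampa: 0.0

leak_reversal:
  l23_pyramidal: -58.0
  l5_pyramidal: -57.0
  basket: -65.0

# Apical-axis extent of an L5 pyramidal cell relative to L2/3; the L2/3 apical
# compartment lengths are rescaled at build time so this holds exactly.
apical_extent_ratio_l5_l23: 2.21

# Compartments longer than this carry one extra internal discretization point.
extra_point_length: 100.0

geometry:
  l5_pyramidal:
    - {name: soma,           length: 39.0,  diam: 28.9, parent: ~,            z_factor: 1.0}
    - {name: apical_trunk,   length: 102.0, diam: 10.2, parent: soma,         z_factor: 1.0}
    - {name: apical_1,       length: 680.0, diam: 7.48, parent: apical_trunk, z_factor: 1.0}
    - {name: apical_2,       length: 680.0, diam: 4.93, parent: apical_1,     z_factor: 1.0}
    - {name: apical_tuft,    length: 425.0, diam: 3.4,  parent: apical_2,     z_factor: 1.0}
    - {name: apical_oblique, length: 255.0, diam: 5.1,  parent: apical_trunk, z_factor: 0.0}
    - {name: basal_1,        length: 85.0,  diam: 6.8,  parent: soma,         z_factor: -1.0}
    - {name: basal_2,        length: 255.0, diam: 8.5,  parent: basal_1,      z_factor: -0.70710678}
    - {name: basal_3,        length: 255.0, diam: 8.5,  parent: basal_1,      z_factor: -0.70710678}
  l23_pyramidal:
    - {name: soma,           length: 22.1,  diam: 23.4, parent: ~,            z_factor: 1.0}
    - {name: apical_trunk,   length: 59.5,  diam: 5.1,  parent: soma,         z_factor: 1.0}
    - {name: apical_1,       length: 306.0, diam: 4.9,  parent: apical_trunk, z_factor: 1.0}
    - {name: apical_tuft,    length: 238.0, diam: 4.08, parent: apical_1,     z_factor: 1.0}
    - {name: apical_oblique, length: 340.0, diam: 3.91, parent: apical_trunk, z_factor: 0.0}
    - {name: basal_1,        length: 85.0,  diam: 4.25, parent: soma,         z_factor: -1.0}
    - {name: basal_2,        length: 255.0, diam: 2.72, parent: basal_1,      z_factor: -0.70710678}
    - {name: basal_3,        length: 255.0, diam: 2.72, parent: basal_1,      z_factor: -0.70710678}
  basket:
    - {name: soma, length: 39.0, diam: 20.0, parent: ~, z_factor: 1.0}

# Maximal conductance densities (mS/cm^2) per compartment.  A compartment
# inherits `default` for its cell type unless overridden.
channels:
  l5_pyramidal:
    default:        {na: 15.0, k: 10.0, leak: 0.042}
    soma:           {na: 150.0, k: 85.0, leak: 0.042, kdr: 3.0, km: 2.0,
                     ca: 0.3, kca: 2.0, cat: 0.1, h: 0.01}
    apical_trunk:   {na: 15.0, k: 10.0, leak: 0.042, km: 0.25, ca: 0.1,
                     kca: 0.5, cat: 0.05, h: 0.02}
    apical_1:       {na: 15.0, k: 10.0, leak: 0.042, km: 0.25, ca: 0.1,
                     kca: 0.5, cat: 0.05, h: 0.03}
    apical_2:       {na: 15.0, k: 10.0, leak: 0.042, km: 0.25, ca: 0.1,
                     kca: 0.5, cat: 0.05, h: 0.04}
    apical_tuft:    {na: 10.0, k: 8.0, leak: 0.042, km: 0.25, h: 0.06, cat: 0.1}
    apical_oblique: {na: 15.0, k: 10.0, leak: 0.042}
    basal_1:        {na: 15.0, k: 10.0, leak: 0.042}
    basal_2:        {na: 15.0, k: 10.0, leak: 0.042}
    basal_3:        {na: 15.0, k: 10.0, leak: 0.042}
  l23_pyramidal:
    default:        {na: 15.0, k: 10.0, leak: 0.04}
    soma:           {na: 150.0, k: 85.0, leak: 0.04, kdr: 3.0, km: 1.0}
    apical_trunk:   {na: 15.0, k: 10.0, leak: 0.04, km: 0.25}
    apical_1:       {na: 15.0, k: 10.0, leak: 0.04, km: 0.25}
    apical_tuft:    {na: 10.0, k: 8.0, leak: 0.04, km: 0.25}
  basket:
    default:        {na: 35.0, k: 9.0, leak: 0.1}

calcium_pool:
  ca0: 0.01          # resting concentration, model units
  tau: 20.0          # ms, relaxation to ca0
  influx_scale: 3.0e-06   # divided by compartment area (cm^2): d[Ca] per nA per ms

synapses:
  ampa:  {rise_tau: 0.5, decay_tau: 5.0, reversal: 0.0}
  gabaa: {rise_tau: 0.5, decay_tau: 5.0, reversal: -80.0}
  delivery_delay: 1.0   # ms, all synapses and exogenous drives

# Baseline renormalization of the current dipole (per pyramidal cell), applied
# over the analysis window.  L2/3: constant offset subtracted.  L5: the line
# slope*t + intercept subtracted.  Calibrated to the resting (drive-free) CD of
# this model.
baseline:
  l2_offset: 5.85353e-06
  l5_slope: -1.69543e-10
  l5_intercept: 4.39029e-05

# Reference kinetics constants (mirrored in the integrator source):
# na:  am=0.32(v+54)/(1-exp(-(v+54)/4)); bm=0.28(v+27)/(exp((v+27)/5)-1)
#      ah=0.128 exp(-(v+50)/18);         bh=4/(1+exp(-(v+27)/5));  I=g m^3 h (v-Ena)
# k:   an=0.032(v+52)/(1-exp(-(v+52)/5)); bn=0.5 exp(-(v+57)/40);  I=g n^4 (v-Ek)
# kdr: ninf=1/(1+exp(-(v+46.3)/3)); tau=3.5;                       I=g n (v-Ek)
# km:  minf=1/(1+exp(-(v+35)/10)); tau=1000/(3.3(exp((v+35)/20)+exp(-(v+35)/20)))
# ca:  am=1.6/(1+exp(-0.072(v-5))); bm=0.02(v+8.9)/(exp((v+8.9)/5)-1); I=g m^2 (v-Eca)
# cat: minf=1/(1+exp(-(v+57)/6.2)); hinf=1/(1+exp((v+81)/4));      I=g m^2 h (v-Eca)
# h:   qinf=1/(1+exp((v+81)/8)); tauq=1/(exp(-14.59-0.086v)+exp(-1.87+0.0701v))
# kca: a=0.01[Ca]; b=0.02; minf=a/(a+b); tau=1/(a+b);              I=g m (v-Ek)

# Voltage offset (mV) applied to the spike-generating Na/K gating of each cell
# type (positive values lower the spike threshold); the slower modulatory
# currents are not shifted.
kinetics_vshift:
  l23_pyramidal: 0.0
  l5_pyramidal: 0.0
  basket: 0.0

# Basket cells use Wang-Buzsaki fast-spiking Na/K kinetics (phi = 5,
# instantaneous Na activation); pyramidal cells use the Traub-Miles forms.
fs_kinetics:
  l23_pyramidal: false
  l5_pyramidal: false
  basket: true

# Conversion from printed drive-current units to model current (nA per unit):
# tonic applied currents are specified in regime tables as model-unit scalars.
current_unit: 0.1666667

# Periodic (toroidal) grid distance wrap length, grid units.
grid_wrap: 10.0
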