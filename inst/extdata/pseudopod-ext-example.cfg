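# Extended pseudopod model: calibrated example configuration.
# Energies (temperature, j-*, lambda-v) and the pseudopod interaction
# parameters are calibration choices of this package, tuned to the regime
# where speed and persistence rise with cell density (see the methods
# vignette); lattice and measurement settings are the desk-scale study
# geometry.

lattice-width = 150
lattice-height = 150
cell-count = 30
total-mcs = 5000
equilibration-mcs = 1000
sample-interval = 1
snapshot-interval = 0
temperature = 15
connectivity-constraint = false
model = pseudopod-ext
j-cell-cell = 6
j-cell-medium = 12
lambda-v = 1
target-area = 250
lambda-persistence = 0.05
decay-time = 10
lambda-act = 200
max-act = 40
n-pseudopods = 3
p-ext = 0.3
p-retr = 0.3
init-dir-strength = 2
cont-dir-strength = 5
max-growth-time = 60
time-between-extensions = 10
retraction-mode = backward
neighboring-actin-bonus = 50
movement-decay-time = 10
pull-strength = 60
tip-bonus = 60
max-distance-for-tip-bonus = 3
touch-behavior = poof-dir
p-touch-retr = 0.1
lateral-threshold = 0.85
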