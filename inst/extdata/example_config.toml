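# btu2d run configuration: flat key = value table of the model symbols.
# Missing keys fall back to the package defaults; unknown keys are errors.

# transport and BBB
D_eff = 5e-11       # effective diffusion coefficient, m^2/s
v     = 5e-7        # ECF bulk flow (+x), m/s
P     = 1e-9        # BBB permeability, m/s

# specific (target) binding
B1max = 5e-2        # umol/L
k1on  = 1           # (umol/L s)^-1
k1off = 1e-2        # s^-1

# non-specific binding
B2max = 50
k2on  = 1e-2
k2off = 1

# dosing (oral)
route = "oral"
F     = 1
Dose  = 30          # umol
ka    = 2e-4        # s^-1
ke    = 5e-5        # s^-1
V     = 20          # L

# domain and grid
xr = 5e-5           # m
yr = 5e-5
nx = 51
ny = 51

# solver / run
rtol = 1e-6
atol = 1e-12
advection_scheme = "central"
t_end = 2e5         # s
snapshot_times = [250, 1000, 5000]
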