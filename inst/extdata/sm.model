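[label] SM
[variables]
p q r s u v w x y z
[parameters]
k1 = 3.3  | 1
k2 = 0.08  | uM
k3 = 0.08  | uM
k4 = 0.5  | 1/(uM s)
k5 = 1.4e-07  | uM/s
k6 = 0.5  | 1/s
k7 = 0.0003  | 1/s
k8 = 0.0005  | 1/s
k9 = 1.4e-07  | uM/s
k10 = 0.5  | 1/s
k11 = 0.00048  | 1/s
k12 = 0.0045  | 1/s
k13 = 0.00067  | 1/s
k14 = 0.000335  | 1/s
k15 = 0.0026  | 1/s
k16 = 5.2e-05  | 1/s
k17 = 0.074  | 1/s
k18 = 0.37  | 1/s
k19 = 0.1  | 1/s
k20 = 0.0006  | 1/s
k21 = 0.0018  | uM
k22 = 0.004  | 1/s
k23 = 0.003  | 1/s
k = 0.065  | uM
h = 2  | 1
[inputs]
k24 = 1
[equations]
p' = k19 * z - k4 * q * p - k15 * p + k16 * r
q' = -k4 * q * p + k6 * u - k8 * q - k13 * q + k14 * s - k17 * w * q
r' = k15 * k1 * p - k4 * s * r - k16 * k1 * r
s' = k13 * k1 * q - k4 * s * r - k8 * s - k14 * k1 * s
u' = k5 * r^h/(r^h + k^h) - k7 * u
v' = k20 * (k21/(k21 + k24 * y)) * (k2 - v) - k24 * k22 * v
w' = k24 * k22 * v - k23 * w
x' = k9 * r^h/(r^h + k^h) - k11 * x
y' = k10 * x - k12 * y
z' = k18 * w * (k3 - p - r/k1) - k19 * z
[init]
p = 0.00381
q = 0.0158
r = 0.00979
s = 0.00544
u = 2.07e-05
v = 0.08
w = 0
x = 6.46e-06
y = 0.000719
z = 0
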