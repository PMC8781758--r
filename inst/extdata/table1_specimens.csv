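# Four-point-bending fatigue test parameters and initial strains, as printed
# in the source study's specimen table. Strains in microstrain; a = lever arm
# (mm); b = inner span (mm); sigma_xx = fatigue stress (MPa); Ne = cycle
# interval; N = cycles to failure. The 'Average' row is the printed one.
specimen,a_mm,b_mm,eps_C_ue,eps_T_ue,sigma_xx_MPa,Ne,N
1,4,34,3157,2953,120,200,8117
2,4,34,2749,2731,120,200,10962
3,4,34,2726,2604,120,200,9279
4,4,34,2644,2544,120,200,12665
Average,4,34,2819,2807,120,200,10270
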