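# Upper-crustal reference values used in detrital corrections of bulk shale
# Mo and U measurements.
# mo_over_al: upper-crust Mo/Al ratio, ppm Mo per wt% Al (Mo = 1.1 ppm over
#   Al = 8.15 wt%, the upper-continental-crust average of Rudnick & Gao);
#   2SD reflects the reported spread of upper-crust Mo estimates.
# u_over_th: upper-crust U/Th mass ratio (dimensionless; U standardized to Th
#   because Th behaves conservatively during weathering and transport, after
#   Cole et al.); 2SD as recommended there.
# d98mo_detr: detrital (upper-crust) d98Mo, permil on the NIST 3134 + 0.25
#   scale, after Voegelin et al.
# d238u_detr: detrital (upper-crust) d238U, permil on the CRM 112a scale,
#   after Weyer et al.
parameter,value,two_sd,units,provenance
mo_over_al,0.135,0.037,ppm per wt%,upper continental crust Mo/Al (Rudnick & Gao compilation)
u_over_th,0.26,0.06,dimensionless,upper continental crust U/Th (Cole et al. Th-normalization)
d98mo_detr,0.15,0,permil,upper crust d98Mo (Voegelin et al.)
d238u_detr,-0.30,0,permil,upper crust d238U (Weyer et al.)
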