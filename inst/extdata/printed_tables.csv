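table_id,metric,arm,value,lo,hi
T2_lifetime,ly,MM,0.92,NA,NA
T2_lifetime,ly,LVAD,4.65,NA,NA
T2_lifetime,ly,incremental,3.73,NA,NA
T2_lifetime,qaly,MM,0.46,NA,NA
T2_lifetime,qaly,LVAD,3.32,NA,NA
T2_lifetime,qaly,incremental,2.86,NA,NA
T2_lifetime,cost,MM,18886,NA,NA
T2_lifetime,cost,LVAD,171621,NA,NA
T2_lifetime,cost,incremental,152735,NA,NA
T2_lifetime,icer_per_ly,incremental,40911,NA,NA
T2_lifetime,icer_per_qaly,incremental,53496,NA,NA
T2_2yr,deaths_pct,MM,91,NA,NA
T2_2yr,deaths_pct,LVAD,25,NA,NA
T2_2yr,deaths_pct,incremental,-66,NA,NA
T2_2yr,ly,MM,0.85,NA,NA
T2_2yr,ly,LVAD,1.71,NA,NA
T2_2yr,ly,incremental,0.87,NA,NA
T2_2yr,qaly,MM,0.43,NA,NA
T2_2yr,qaly,LVAD,1.23,NA,NA
T2_2yr,qaly,incremental,0.80,NA,NA
T2_2yr,cost,MM,17173,NA,NA
T2_2yr,cost,LVAD,121843,NA,NA
T2_2yr,cost,incremental,104670,NA,NA
T2_2yr,icer_per_ly,incremental,120868,NA,NA
T2_2yr,icer_per_qaly,incremental,131593,NA,NA
T2_5yr,deaths_pct,MM,100,NA,NA
T2_5yr,deaths_pct,LVAD,54,NA,NA
T2_5yr,deaths_pct,incremental,-46,NA,NA
T2_5yr,ly,MM,0.92,NA,NA
T2_5yr,ly,LVAD,3.30,NA,NA
T2_5yr,ly,incremental,2.38,NA,NA
T2_5yr,qaly,MM,0.46,NA,NA
T2_5yr,qaly,LVAD,2.36,NA,NA
T2_5yr,qaly,incremental,1.90,NA,NA
T2_5yr,cost,MM,18855,NA,NA
T2_5yr,cost,LVAD,148002,NA,NA
T2_5yr,cost,incremental,129148,NA,NA
T2_5yr,icer_per_ly,incremental,54314,NA,NA
T2_5yr,icer_per_qaly,incremental,67997,NA,NA
T3,qaly,MM,0.46,NA,NA
T3,absolute_shortfall,all,10.38,NA,NA
T3,proportional_shortfall,all,0.96,NA,NA
T3,weight,all,1.7,NA,NA
T3,icer_per_qaly,incremental,53496,NA,NA
T3,weighted_icer,incremental,31468,NA,NA
T4,ly,MM,0.92,NA,NA
T4,ly,LVAD,4.58,NA,NA
T4,ly,incremental,3.66,NA,NA
T4,qaly,MM,0.46,NA,NA
T4,qaly,LVAD,3.26,NA,NA
T4,qaly,incremental,2.80,NA,NA
T4,cost,MM,18886,NA,NA
T4,cost,LVAD,166433,NA,NA
T4,cost,incremental,147547,NA,NA
T4,icer_per_ly,incremental,40351,NA,NA
T4,icer_per_qaly,incremental,52762,NA,NA
T5,ly,MM,0.93,0.80,1.08
T5,ly,LVAD,4.59,4.14,5.10
T5,ly,incremental,3.67,3.19,4.19
T5,qaly,MM,0.48,0.41,0.55
T5,qaly,LVAD,3.26,2.94,3.61
T5,qaly,incremental,2.78,2.46,3.14
T5,cost,MM,18953,17107,21016
T5,cost,LVAD,171281,144725,200692
T5,cost,incremental,152329,125665,181812
T5,icer_per_qaly,incremental,54748,NA,NA
T5,p_ce_30k,all,0,NA,NA
T6_I1,ly,MM,0.37,NA,NA
T6_I1,ly,LVAD,3.05,NA,NA
T6_I1,ly,incremental,2.68,NA,NA
T6_I1,qaly,MM,0.06,NA,NA
T6_I1,qaly,LVAD,1.65,NA,NA
T6_I1,qaly,incremental,1.59,NA,NA
T6_I1,cost,MM,13333,NA,NA
T6_I1,cost,LVAD,148214,NA,NA
T6_I1,cost,incremental,134882,NA,NA
T6_I1,icer_per_ly,incremental,50336,NA,NA
T6_I1,icer_per_qaly,incremental,84800,NA,NA
T6_I23,ly,MM,0.92,NA,NA
T6_I23,ly,LVAD,3.93,NA,NA
T6_I23,ly,incremental,3.01,NA,NA
T6_I23,qaly,MM,0.36,NA,NA
T6_I23,qaly,LVAD,2.54,NA,NA
T6_I23,qaly,incremental,2.17,NA,NA
T6_I23,cost,MM,18886,NA,NA
T6_I23,cost,LVAD,161052,NA,NA
T6_I23,cost,incremental,142166,NA,NA
T6_I23,icer_per_ly,incremental,47198,NA,NA
T6_I23,icer_per_qaly,incremental,65458,NA,NA
T6_I45,ly,MM,1.00,NA,NA
T6_I45,ly,LVAD,4.14,NA,NA
T6_I45,ly,incremental,3.14,NA,NA
T6_I45,qaly,MM,0.51,NA,NA
T6_I45,qaly,LVAD,2.96,NA,NA
T6_I45,qaly,incremental,2.45,NA,NA
T6_I45,cost,MM,19714,NA,NA
T6_I45,cost,LVAD,163958,NA,NA
T6_I45,cost,incremental,144244,NA,NA
T6_I45,icer_per_ly,incremental,45967,NA,NA
T6_I45,icer_per_qaly,incremental,58815,NA,NA
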