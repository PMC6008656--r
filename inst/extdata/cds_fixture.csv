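"id","category","quantity","pool","species","conjugation","sulfated","value","unit","group_id","group_size","reconstructed"
"composition_plasma_CA","composition","composition","plasma","CA",NA,FALSE,0.3,"-","comp_plasma",6,TRUE
"composition_plasma_CDCA","composition","composition","plasma","CDCA",NA,FALSE,0.35,"-","comp_plasma",6,TRUE
"composition_plasma_DCA","composition","composition","plasma","DCA",NA,FALSE,0.2,"-","comp_plasma",6,TRUE
"composition_plasma_UDCA","composition","composition","plasma","UDCA",NA,FALSE,0.05,"-","comp_plasma",6,TRUE
"composition_plasma_LCA","composition","composition","plasma","LCA",NA,FALSE,0.03,"-","comp_plasma",6,TRUE
"composition_plasma_O","composition","composition","plasma","O",NA,FALSE,0.07,"-","comp_plasma",6,TRUE
"composition_portal_CA","composition","composition","portal","CA",NA,FALSE,0.32,"-","comp_portal",6,TRUE
"composition_portal_CDCA","composition","composition","portal","CDCA",NA,FALSE,0.33,"-","comp_portal",6,TRUE
"composition_portal_DCA","composition","composition","portal","DCA",NA,FALSE,0.22,"-","comp_portal",6,TRUE
"composition_portal_UDCA","composition","composition","portal","UDCA",NA,FALSE,0.05,"-","comp_portal",6,TRUE
"composition_portal_LCA","composition","composition","portal","LCA",NA,FALSE,0.03,"-","comp_portal",6,TRUE
"composition_portal_O","composition","composition","portal","O",NA,FALSE,0.05,"-","comp_portal",6,TRUE
"composition_liver_CA","composition","composition","liver","CA",NA,FALSE,0.35,"-","comp_liver",6,TRUE
"composition_liver_CDCA","composition","composition","liver","CDCA",NA,FALSE,0.35,"-","comp_liver",6,TRUE
"composition_liver_DCA","composition","composition","liver","DCA",NA,FALSE,0.2,"-","comp_liver",6,TRUE
"composition_liver_UDCA","composition","composition","liver","UDCA",NA,FALSE,0.04,"-","comp_liver",6,TRUE
"composition_liver_LCA","composition","composition","liver","LCA",NA,FALSE,0.02,"-","comp_liver",6,TRUE
"composition_liver_O","composition","composition","liver","O",NA,FALSE,0.04,"-","comp_liver",6,TRUE
"composition_gallbladder_CA","composition","composition","gallbladder","CA",NA,FALSE,0.38,"-","comp_gallbladder",6,TRUE
"composition_gallbladder_CDCA","composition","composition","gallbladder","CDCA",NA,FALSE,0.34,"-","comp_gallbladder",6,TRUE
"composition_gallbladder_DCA","composition","composition","gallbladder","DCA",NA,FALSE,0.2,"-","comp_gallbladder",6,TRUE
"composition_gallbladder_UDCA","composition","composition","gallbladder","UDCA",NA,FALSE,0.04,"-","comp_gallbladder",6,TRUE
"composition_gallbladder_LCA","composition","composition","gallbladder","LCA",NA,FALSE,0.01,"-","comp_gallbladder",6,TRUE
"composition_gallbladder_O","composition","composition","gallbladder","O",NA,FALSE,0.03,"-","comp_gallbladder",6,TRUE
"composition_feces_CA","composition","composition","feces","CA",NA,FALSE,0.05,"-","comp_feces",6,TRUE
"composition_feces_CDCA","composition","composition","feces","CDCA",NA,FALSE,0.05,"-","comp_feces",6,TRUE
"composition_feces_DCA","composition","composition","feces","DCA",NA,FALSE,0.45,"-","comp_feces",6,TRUE
"composition_feces_UDCA","composition","composition","feces","UDCA",NA,FALSE,0.05,"-","comp_feces",6,TRUE
"composition_feces_LCA","composition","composition","feces","LCA",NA,FALSE,0.35,"-","comp_feces",6,TRUE
"composition_feces_O","composition","composition","feces","O",NA,FALSE,0.05,"-","comp_feces",6,TRUE
"composition_synthesis_CA","composition","composition","synthesis","CA",NA,FALSE,0.45,"-","comp_synthesis",3,TRUE
"composition_synthesis_CDCA","composition","composition","synthesis","CDCA",NA,FALSE,0.45,"-","comp_synthesis",3,TRUE
"composition_synthesis_O","composition","composition","synthesis","O",NA,FALSE,0.1,"-","comp_synthesis",3,TRUE
"conjugation_plasma_u","conjugation","conjugation","plasma",NA,"u",FALSE,0.35,"-","conj_plasma",3,TRUE
"conjugation_plasma_g","conjugation","conjugation","plasma",NA,"g",FALSE,0.5,"-","conj_plasma",3,TRUE
"conjugation_plasma_t","conjugation","conjugation","plasma",NA,"t",FALSE,0.15,"-","conj_plasma",3,TRUE
"conjugation_bile_u","conjugation","conjugation","bile",NA,"u",FALSE,0.03,"-","conj_bile",3,TRUE
"conjugation_bile_g","conjugation","conjugation","bile",NA,"g",FALSE,0.72,"-","conj_bile",3,TRUE
"conjugation_bile_t","conjugation","conjugation","bile",NA,"t",FALSE,0.25,"-","conj_bile",3,TRUE
"conjugation_liver_u","conjugation","conjugation","liver",NA,"u",FALSE,0.1,"-","conj_liver",3,TRUE
"conjugation_liver_g","conjugation","conjugation","liver",NA,"g",FALSE,0.67,"-","conj_liver",3,TRUE
"conjugation_liver_t","conjugation","conjugation","liver",NA,"t",FALSE,0.23,"-","conj_liver",3,TRUE
"conjugation_feces_u","conjugation","conjugation","feces",NA,"u",FALSE,0.95,"-","conj_feces",3,TRUE
"conjugation_feces_g","conjugation","conjugation","feces",NA,"g",FALSE,0.03,"-","conj_feces",3,TRUE
"conjugation_feces_t","conjugation","conjugation","feces",NA,"t",FALSE,0.02,"-","conj_feces",3,TRUE
"sulfation_LCA_plasma","sulfation","sulfation","plasma","LCA",NA,TRUE,0.6,"-","sulfation_LCA_plasma",1,TRUE
"sulfation_LCA_bile","sulfation","sulfation","bile","LCA",NA,TRUE,0.3,"-","sulfation_LCA_bile",1,TRUE
"sulfation_LCA_feces","sulfation","sulfation","feces","LCA",NA,TRUE,0.3,"-","sulfation_LCA_feces",1,TRUE
"sulfation_total_plasma","sulfation","sulfation","plasma","total",NA,TRUE,0.02,"-","sulfation_total_plasma",1,TRUE
"sulfation_total_bile","sulfation","sulfation","bile","total",NA,TRUE,0.005,"-","sulfation_total_bile",1,TRUE
"sulfation_total_feces","sulfation","sulfation","feces","total",NA,TRUE,0.1,"-","sulfation_total_feces",1,TRUE
"pool_total","pools","pool","total",NA,NA,FALSE,3500,"umol","pool_total",1,TRUE
"pool_CA","pools","pool","CA",NA,NA,FALSE,1225,"umol","pool_CA",1,TRUE
"pool_CDCA","pools","pool","CDCA",NA,NA,FALSE,1225,"umol","pool_CDCA",1,TRUE
"pool_DCA","pools","pool","DCA",NA,NA,FALSE,800,"umol","pool_DCA",1,TRUE
"pool_plasma","pools","pool","plasma",NA,NA,FALSE,9,"umol","pool_plasma",1,TRUE
"pool_portal","pools","pool","portal",NA,NA,FALSE,6,"umol","pool_portal",1,TRUE
"pool_liver","pools","pool","liver",NA,NA,FALSE,80,"umol","pool_liver",1,TRUE
"pool_gallbladder","pools","pool","gallbladder",NA,NA,FALSE,1400,"umol","pool_gallbladder",1,TRUE
"flux_synthesis","fluxes","flux",NA,NA,NA,FALSE,680,"umol/day","flux_synthesis",1,TRUE
"flux_biliary_output","fluxes","flux",NA,NA,NA,FALSE,20650,"umol/day","flux_biliary_output",1,TRUE
"fcr_CA","fluxes","fcr",NA,"CA",NA,FALSE,0.28,"1/day","fcr_CA",1,TRUE
"fcr_CDCA","fluxes","fcr",NA,"CDCA",NA,FALSE,0.25,"1/day","fcr_CDCA",1,TRUE
"fcr_DCA","fluxes","fcr",NA,"DCA",NA,FALSE,0.38,"1/day","fcr_DCA",1,TRUE
"pp_total_fold30","postprandial","pp",NA,NA,NA,FALSE,1.5,"-","pp_total_fold30",1,TRUE
"pp_total_foldpeak","postprandial","pp",NA,NA,NA,FALSE,3.2,"-","pp_total_foldpeak",1,FALSE
"pp_total_tpeak","postprandial","pp",NA,NA,NA,FALSE,90,"min","pp_total_tpeak",1,FALSE
"pp_conj_fold30","postprandial","pp",NA,NA,NA,FALSE,1.6,"-","pp_conj_fold30",1,TRUE
"pp_conj_foldpeak","postprandial","pp",NA,NA,NA,FALSE,3.8,"-","pp_conj_foldpeak",1,TRUE
"pp_conj_tpeak","postprandial","pp",NA,NA,NA,FALSE,90,"min","pp_conj_tpeak",1,TRUE
"pp_unconj_fold30","postprandial","pp",NA,NA,NA,FALSE,1.15,"-","pp_unconj_fold30",1,TRUE
"pp_unconj_foldpeak","postprandial","pp",NA,NA,NA,FALSE,1.6,"-","pp_unconj_foldpeak",1,TRUE
"pp_unconj_tpeak","postprandial","pp",NA,NA,NA,FALSE,120,"min","pp_unconj_tpeak",1,TRUE
"transit_si_fasting","transit","transit",NA,NA,NA,FALSE,5.5,"h","transit_si_fasting",1,TRUE
"transit_si_postprandial","transit","transit",NA,NA,NA,FALSE,3.5,"h","transit_si_postprandial",1,TRUE
"transit_colon","transit","transit",NA,NA,NA,FALSE,30,"h","transit_colon",1,TRUE
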