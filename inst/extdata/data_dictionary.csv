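"name","type","min","max","description"
"participant_id","character",NA,NA,"opaque participant identifier (no commas)"
"sex","sex",NA,NA,"male|female; norm stratification"
"education_years","integer",0,40,"completed years of education; banded low <10, medium 10-<15, high 15+"
"age_years","integer",0,120,"age at wave 4"
"sdmt_w3","numeric",NA,NA,"raw test score, wave 3"
"sdmt_w4","numeric",NA,NA,"raw test score, wave 4"
"tmt_a_w3","numeric",NA,NA,"raw test score, wave 3"
"tmt_a_w4","numeric",NA,NA,"raw test score, wave 4"
"srt_w3","numeric",NA,NA,"raw test score, wave 3"
"srt_w4","numeric",NA,NA,"raw test score, wave 4"
"crt_w3","numeric",NA,NA,"raw test score, wave 3"
"crt_w4","numeric",NA,NA,"raw test score, wave 4"
"digits_back_w3","numeric",NA,NA,"raw test score, wave 3"
"digits_back_w4","numeric",NA,NA,"raw test score, wave 4"
"tmt_b_w3","numeric",NA,NA,"raw test score, wave 3"
"tmt_b_w4","numeric",NA,NA,"raw test score, wave 4"
"stroop_w3","numeric",NA,NA,"raw test score, wave 3"
"stroop_w4","numeric",NA,NA,"raw test score, wave 4"
"zoo_map_w3","numeric",NA,NA,"raw test score, wave 3"
"zoo_map_w4","numeric",NA,NA,"raw test score, wave 4"
"dice_w3","numeric",NA,NA,"raw test score, wave 3"
"dice_w4","numeric",NA,NA,"raw test score, wave 4"
"cvlt_immediate_w3","numeric",NA,NA,"raw test score, wave 3"
"cvlt_immediate_w4","numeric",NA,NA,"raw test score, wave 4"
"cvlt_delayed_w3","numeric",NA,NA,"raw test score, wave 3"
"cvlt_delayed_w4","numeric",NA,NA,"raw test score, wave 4"
"bvrt_b_w3","numeric",NA,NA,"raw test score, wave 3"
"bvrt_b_w4","numeric",NA,NA,"raw test score, wave 4"
"cowat_w3","numeric",NA,NA,"raw test score, wave 3"
"cowat_w4","numeric",NA,NA,"raw test score, wave 4"
"bnt15_w3","numeric",NA,NA,"raw test score, wave 3"
"bnt15_w4","numeric",NA,NA,"raw test score, wave 4"
"stw_w3","numeric",NA,NA,"raw test score, wave 3"
"stw_w4","numeric",NA,NA,"raw test score, wave 4"
"purdue_pegboard_w3","numeric",NA,NA,"raw test score, wave 3"
"purdue_pegboard_w4","numeric",NA,NA,"raw test score, wave 4"
"iat_w3","numeric",NA,NA,"raw test score, wave 3"
"iat_w4","numeric",NA,NA,"raw test score, wave 4"
"bvrt_c_w3","numeric",NA,NA,"raw test score, wave 3"
"bvrt_c_w4","numeric",NA,NA,"raw test score, wave 4"
"rmie_w3","numeric",NA,NA,"raw test score, wave 3"
"rmie_w4","numeric",NA,NA,"raw test score, wave 4"
"mmse_w3","integer",0,30,"Mini-Mental State Examination, wave 3"
"mmse_w4","integer",0,30,"Mini-Mental State Examination, wave 4"
"macq_total","integer",7,35,"Memory and Cognition Questionnaire total (subjective complaint; >24 = decline)"
"phq9_total","integer",0,27,"PHQ-9 depression screen (>=10 = possible depressive explanation)"
"hrs_iadl_memory_problem","tristate",NA,NA,"self-report: IADL problems due to memory"
"needs_care_help","tristate",NA,NA,"self-report: needs household/personal care help"
"informant_available","logical",NA,NA,"TRUE if an informant interview exists; if FALSE all informant fields are empty"
"iqcode_mean","numeric",1,5,"informant IQCODE mean (1-5; >3.31 = observed decline)"
"bayer_iadl_mean","numeric",1,10,"informant Bayer IADL mean (1-10; >3.12 = interference)"
"bayer_item2_difficulty","tristate",NA,NA,"informant: difficulty on this Bayer IADL item"
"bayer_item4_difficulty","tristate",NA,NA,"informant: difficulty on this Bayer IADL item"
"bayer_item11_difficulty","tristate",NA,NA,"informant: difficulty on this Bayer IADL item"
"dexq_item9","integer",0,4,"informant DEX-Q item frequency 0=never..4=very often; >=2 = sometimes or more"
"dexq_item11","integer",0,4,"informant DEX-Q item frequency 0=never..4=very often; >=2 = sometimes or more"
"dexq_item13","integer",0,4,"informant DEX-Q item frequency 0=never..4=very often; >=2 = sometimes or more"
"dexq_item20","integer",0,4,"informant DEX-Q item frequency 0=never..4=very often; >=2 = sometimes or more"
"behave_out_of_character","tristate",NA,NA,"informant endorsement: social/behavioural change"
"unaware_others_feelings","tristate",NA,NA,"informant endorsement: social/behavioural change"
"less_social_participation","tristate",NA,NA,"informant endorsement: social/behavioural change"
"lost_skills_hobbies","tristate",NA,NA,"informant endorsement: social/behavioural change"
"difficulty_familiar_tasks","tristate",NA,NA,"informant endorsement: everyday praxis/object-recognition difficulty"
"difficulty_familiar_tools","tristate",NA,NA,"informant endorsement: everyday praxis/object-recognition difficulty"
"lost_in_familiar_places","tristate",NA,NA,"informant endorsement: everyday praxis/object-recognition difficulty"
"informant_worsening","tristate",NA,NA,"informant reports worsening everyday cognition"
"doctor_consult_cognition","tristate",NA,NA,"recent doctor consultation about cognitive change"
"history_psychosis","tristate",NA,NA,"informant-reported history of schizophrenia/other psychosis"
"prior_path_diagnosis","prior",NA,NA,"none|mci_like|dementia: prior study diagnosis"
"onset_months_ago","numeric",0,Inf,"months since cognitive difficulties began"
"delirium_signs","tristate",NA,NA,"informant-reported delirium signs"
"delirium_duration_months","numeric",0,Inf,"duration of delirium signs, months"
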