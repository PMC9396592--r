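description,feature_kind,targets,action
"Change distance requirements for community care (MISSION Act)",parameter_on_exogenous,,retune
"Broaden benefits eligibility (service connection, disability)",parameter_on_exogenous,,retune
"Increase staffing at VA Office of Community Care",buffer_capacity,R3,weaken
"Improve technological aspects of communication (switch from fax machines)",stock_flow_structure,,retune
"Extend time between primary care authorization renewals",delay,B3|B4,add
"Reduce delays for specialty care authorizations and appointments (evening and weekend availability)",delay,B6|B1|B2,weaken
"Improve record sharing and provider communication",balancing_loop,B12|B13,strengthen
"Veteran identification in non-VA clinics",balancing_loop,B7,strengthen
"Reduce VA provider burnout and improve retention to improve continuity of VA care",reinforcing_loop,R1|B9,weaken
"Improve VA communication about processes and online systems for tracking care",information_link,B3|B4|B6|B12|B13,strengthen
"Change rules disincentivizing rural staffing; increase VA budget; allow VA benefits as secondary insurance",rule,B9|R2,retune
"Reduce administrative barriers to process redesign; offer case management and navigation services; form community coalitions",self_organization,,add
"Change VA's conflicting incentives between improving access to care and keeping funding inside VA",goal,,retune
"Single-payer system (e.g., Australian gold card)",paradigm,,add
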