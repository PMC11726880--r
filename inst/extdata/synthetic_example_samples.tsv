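sample_id	group
case_01	case
case_02	case
case_03	case
case_04	case
case_05	case
ctrl_01	control
ctrl_02	control
ctrl_03	control
ctrl_04	control
ctrl_05	control
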